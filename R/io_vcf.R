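# Minimal VCFv4.2 dialect used throughout the package.
#
# One biallelic record per line. INFO carries TYPE (SNV/INS/DEL/MNV),
# LEN = |len(alt) - len(ref)| (0 for SNV/MNV), SCORE = somatic probability
# when a model was applied, and for simulated truth sets ORIGIN and TVAF.
# FORMAT is GT:AD:DP with samples ordered [normal, tumor]. FILTER is PASS or
# LowScore. Coordinates are 1-based only in this file format; everything
# internal is 0-based half-open.

#' Construct a VCF record frame
#'
#' @param chrom,pos,ref,alt Per-record fields; `pos` is 1-based.
#' @param filter FILTER column values (default `"PASS"`).
#' @param score Somatic probability in `[0,1]` or NA.
#' @param gt_normal,ad_ref_normal,ad_alt_normal,dp_normal Normal-sample
#'   genotype fields (and analogously `_tumor`).
#' @param origin,tvaf Optional truth-set annotations (variant origin and
#'   simulated tumor VAF).
#' @return data.frame of class `vcf_records`.
#' @export
vcf_records <- function(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        filter = rep("PASS", length(pos)),
                        score = rep(NA_real_, length(pos)),
                        gt_normal = rep("./.", length(pos)),
                        ad_ref_normal = rep(0L, length(pos)),
                        ad_alt_normal = rep(0L, length(pos)),
                        dp_normal = rep(0L, length(pos)),
                        gt_tumor = rep("./.", length(pos)),
                        ad_ref_tumor = rep(0L, length(pos)),
                        ad_alt_tumor = rep(0L, length(pos)),
                        dp_tumor = rep(0L, length(pos)),
                        origin = rep(NA_character_, length(pos)),
                        tvaf = rep(NA_real_, length(pos))) {
  stopifnot(all(nchar(ref) > 0), all(nchar(alt) > 0))
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = toupper(ref), alt = toupper(alt),
                   filter = filter,
                   vtype = variant_type(ref, alt),
                   vlen = abs(nchar(alt) - nchar(ref)),
                   score = as.numeric(score),
                   gt_normal = gt_normal,
                   ad_ref_normal = as.integer(ad_ref_normal),
                   ad_alt_normal = as.integer(ad_alt_normal),
                   dp_normal = as.integer(dp_normal),
                   gt_tumor = gt_tumor,
                   ad_ref_tumor = as.integer(ad_ref_tumor),
                   ad_alt_tumor = as.integer(ad_alt_tumor),
                   dp_tumor = as.integer(dp_tumor),
                   origin = as.character(origin),
                   tvaf = as.numeric(tvaf),
                   stringsAsFactors = FALSE)
  class(df) <- c("vcf_records", "data.frame")
  df
}

#' Classify ref/alt allele pairs
#' @return Character vector in `c("SNV", "INS", "DEL", "MNV")`.
#' @export
variant_type <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  ifelse(nr == 1 & na == 1, "SNV",
         ifelse(na > nr, "INS", ifelse(nr > na, "DEL", "MNV")))
}

format_num <- function(x) {
  ifelse(is.na(x), ".", sprintf("%.6g", x))
}

#' Write a VCF file
#'
#' Records must be sorted by (chrom, pos); the writer refuses unsorted input.
#' The output is bit-deterministic for identical inputs and round-trips
#' through [read_vcf()].
#'
#' @param records A `vcf_records` frame.
#' @param sample_names Length-2 character, `[normal, tumor]`.
#' @param reference_name Reference label for the header.
#' @param path Output path.
#' @param contig_lengths Optional named integer vector for `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, sample_names = c("NORMAL", "TUMOR"),
                      reference_name = "reference", path,
                      contig_lengths = NULL) {
  stopifnot(length(sample_names) == 2)
  n <- nrow(records)
  if (n > 1) {
    o <- order(records$chrom, records$pos)
    if (!identical(o, seq_len(n))) stop("records not sorted by (chrom, pos)")
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##reference=", reference_name),
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    "##FILTER=<ID=PASS,Description=\"Somatic call passing the score threshold\">",
    "##FILTER=<ID=LowScore,Description=\"Not a confident somatic call\">",
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type: SNV, INS, DEL or MNV\">",
    "##INFO=<ID=LEN,Number=1,Type=Integer,Description=\"Absolute allele length difference\">",
    "##INFO=<ID=SCORE,Number=1,Type=Float,Description=\"Somatic probability from the boosting model\">",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"Simulated variant origin (somatic or germline)\">",
    "##INFO=<ID=TVAF,Number=1,Type=Float,Description=\"Simulated tumor variant allele fraction\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref and alt allele read counts\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth at the locus\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
  lines <- hdr
  if (n > 0) {
    info <- paste0("TYPE=", records$vtype, ";LEN=", records$vlen)
    has_score <- !is.na(records$score)
    info[has_score] <- paste0(info[has_score], ";SCORE=",
                              format_num(records$score[has_score]))
    has_origin <- !is.na(records$origin)
    info[has_origin] <- paste0(info[has_origin], ";ORIGIN=",
                               records$origin[has_origin])
    has_tvaf <- !is.na(records$tvaf)
    info[has_tvaf] <- paste0(info[has_tvaf], ";TVAF=",
                             format_num(records$tvaf[has_tvaf]))
    bad <- records$ad_ref_normal + records$ad_alt_normal > records$dp_normal |
      records$ad_ref_tumor + records$ad_alt_tumor > records$dp_tumor
    if (any(bad)) stop("AD components exceed DP at record ", which(bad)[1])
    fmt_n <- paste0(records$gt_normal, ":", records$ad_ref_normal, ",",
                    records$ad_alt_normal, ":", records$dp_normal)
    fmt_t <- paste0(records$gt_tumor, ":", records$ad_ref_tumor, ",",
                    records$ad_alt_tumor, ":", records$dp_tumor)
    lines <- c(lines, paste(records$chrom, records$pos, ".", records$ref,
                            records$alt, ".", records$filter, info, "GT:AD:DP",
                            fmt_n, fmt_t, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF file written in the package dialect
#'
#' @param path VCF path.
#' @return A `vcf_records` frame.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) return(vcf_records())
  f <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  info <- get(8)
  info_val <- function(key) {
    m <- stringi::stri_match_first_regex(info,
      paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    m
  }
  parse_sample <- function(col) {
    parts <- strsplit(col, ":", fixed = TRUE)
    gt <- vapply(parts, `[[`, character(1), 1)
    ad <- strsplit(vapply(parts, `[[`, character(1), 2), ",", fixed = TRUE)
    list(gt = gt,
         ad_ref = as.integer(vapply(ad, `[[`, character(1), 1)),
         ad_alt = as.integer(vapply(ad, `[[`, character(1), 2)),
         dp = as.integer(vapply(parts, `[[`, character(1), 3)))
  }
  ns <- parse_sample(get(10))
  ts <- parse_sample(get(11))
  vcf_records(chrom = get(1), pos = as.integer(get(2)), ref = get(4),
              alt = get(5), filter = get(7),
              score = suppressWarnings(as.numeric(info_val("SCORE"))),
              gt_normal = ns$gt, ad_ref_normal = ns$ad_ref,
              ad_alt_normal = ns$ad_alt, dp_normal = ns$dp,
              gt_tumor = ts$gt, ad_ref_tumor = ts$ad_ref,
              ad_alt_tumor = ts$ad_alt, dp_tumor = ts$dp,
              origin = info_val("ORIGIN"),
              tvaf = suppressWarnings(as.numeric(info_val("TVAF"))))
}

#' Read a 3-column BED file (0-based half-open)
#'
#' @param path BED path.
#' @return data.frame with columns chrom, start, end.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3)) stop("malformed BED line (need 3 columns)")
  df <- data.frame(chrom = vapply(f, `[[`, character(1), 1),
                   start = as.integer(vapply(f, `[[`, character(1), 2)),
                   end = as.integer(vapply(f, `[[`, character(1), 3)),
                   stringsAsFactors = FALSE)
  if (any(is.na(df$start)) || any(is.na(df$end)) || any(df$end < df$start)) {
    stop("malformed BED coordinates")
  }
  df
}
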