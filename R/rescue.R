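# Cross-platform ("two-tech") truth-set rescue: match two call sets, count
# cross-platform allele support from the other platform's alignments, and
# classify each variant as COMMON / LR_ORIGIN / ILMN_ORIGIN / DROPPED.

#' Match two call sets by normalized exact comparison
#'
#' Variants equal on (chrom, pos, ref, alt) after left-normalization against
#' the reference are common; the partition is exact and disjoint.
#'
#' @param set_a,set_b `vcf_records` frames.
#' @param reference Indexed FASTA path (for normalization).
#' @return List with `common`, `a_only`, `b_only` (normalized records; the
#'   common set keeps set_a's rows).
#' @export
match_callsets <- function(set_a, set_b, reference) {
  na <- normalize_records(set_a, reference)
  nb <- normalize_records(set_b, reference)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  ka <- key(na)
  kb <- key(nb)
  list(common = na[ka %in% kb, , drop = FALSE],
       a_only = na[!ka %in% kb, , drop = FALSE],
       b_only = nb[!kb %in% ka, , drop = FALSE])
}

# left-normalize records against the reference (window = 1 kb around each)
normalize_records <- function(records, reference) {
  if (nrow(records) == 0) return(records)
  lens <- reference_lengths(reference)
  for (i in seq_len(nrow(records))) {
    chrom <- records$chrom[i]
    ws <- max(0L, records$pos[i] - 1L - 500L)
    we <- min(lens[[chrom]], records$pos[i] - 1L + nchar(records$ref[i]) + 500L)
    win <- read_reference_window(reference, chrom, ws, we)
    nv <- left_normalize(records$pos[i], records$ref[i], records$alt[i],
                         win, ws)
    records$pos[i] <- nv$pos
    records$ref[i] <- nv$ref
    records$alt[i] <- nv$alt
  }
  records$vtype <- variant_type(records$ref, records$alt)
  records$vlen <- abs(nchar(records$alt) - nchar(records$ref))
  o <- order(records$chrom, records$pos, records$ref, records$alt)
  records <- records[o, , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Count cross-platform allele support at a variant locus
#'
#' Direct pileup-style counting from an alignment file: coverage is the
#' number of passing reads whose aligned span covers the variant locus;
#' alt reads are those carrying the exact alternate allele with one matching
#' flank base on each side (indels compared across the aligned span).
#'
#' @param bam_path Indexed BAM.
#' @param variant One-row data.frame or list with chrom, pos (1-based), ref,
#'   alt.
#' @param reference Indexed FASTA path.
#' @param min_baseq Minimum base quality over the allele span.
#' @param min_mapq Minimum mapping quality.
#' @return List with `alt_reads` and `coverage`.
#' @export
cross_support <- function(bam_path, variant, reference, min_baseq = 10L,
                          min_mapq = 10L) {
  chrom <- variant$chrom
  pos0 <- variant$pos - 1L
  ref_len <- nchar(variant$ref)
  lens <- reference_lengths(reference)
  reads <- load_reads(bam_path, chrom, max(0L, pos0 - 1L),
                      min(lens[[chrom]], pos0 + ref_len + 1L),
                      min_mapq = min_mapq, sample = "tumor")
  if (nrow(reads) == 0) return(list(alt_reads = 0L, coverage = 0L))
  # expected read sequence across the locus when carrying the alt allele,
  # with one flank base on each side
  a <- pos0 - 1L                     # 0-based flank base before the allele
  b <- pos0 + ref_len                # 0-based flank base after the allele
  if (a < 0 || b >= lens[[chrom]]) return(list(alt_reads = 0L, coverage = 0L))
  left <- read_reference_window(reference, chrom, a, a + 1L)
  right <- read_reference_window(reference, chrom, b, b + 1L)
  alt_expect <- paste0(left, variant$alt, right)
  coverage <- 0L
  alt_reads <- 0L
  for (i in seq_len(nrow(reads))) {
    map <- cigar_ref_to_read(reads$cigar[i], reads$start[i])
    span <- map$ref_span
    if (!(span[1] <= pos0 && span[2] >= pos0 + max(ref_len, 1L))) next
    coverage <- coverage + 1L
    ra <- map$lookup(a)
    rb <- map$lookup(b)
    if (is.na(ra) || is.na(rb)) next
    sub <- substring(reads$sequence[i], ra, rb)
    if (sub != alt_expect) next
    q <- string_to_phred(reads$qual[i])
    if (min(q[ra:rb]) < min_baseq) next
    alt_reads <- alt_reads + 1L
  }
  list(alt_reads = alt_reads, coverage = coverage)
}

# ref-position -> read-index map from a CIGAR (M/=/X consume both; I/S read
# only; D/N ref only). Returns closure lookup(ref_pos0) -> read idx (1-based)
# and the covered ref span [start, end).
cigar_ref_to_read <- function(cigar, start0) {
  ops <- parse_cigar(cigar)
  ref_pos <- integer(0)
  read_idx <- integer(0)
  r <- start0
  q <- 1L
  for (i in seq_len(nrow(ops))) {
    len <- ops$len[i]
    op <- ops$op[i]
    if (op %in% c("M", "=", "X")) {
      ref_pos <- c(ref_pos, r:(r + len - 1L))
      read_idx <- c(read_idx, q:(q + len - 1L))
      r <- r + len
      q <- q + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      r <- r + len
    }
  }
  span <- if (length(ref_pos)) c(min(ref_pos), max(ref_pos) + 1L) else c(0L, 0L)
  lookup <- function(p) {
    j <- match(p, ref_pos)
    if (is.na(j)) NA_integer_ else read_idx[j]
  }
  list(lookup = lookup, ref_span = span)
}

#' Classify a variant into a two-tech truth category
#'
#' Variants present in both call sets are COMMON regardless of support;
#' platform-unique variants are rescued (LR_ORIGIN / ILMN_ORIGIN) iff the
#' other platform's alignments show at least `min_alt` alt reads at
#' coverage >= `min_cov`, else DROPPED.
#'
#' @param membership One of "both", "long_only", "short_only".
#' @param support List with `alt_reads` and `coverage` (ignored for "both").
#' @param min_alt,min_cov Rescue thresholds (defaults 2 and 20).
#' @return One of "COMMON", "LR_ORIGIN", "ILMN_ORIGIN", "DROPPED".
#' @export
classify <- function(membership, support, min_alt = 2L, min_cov = 20L) {
  membership <- match.arg(membership, c("both", "long_only", "short_only"))
  if (membership == "both") return("COMMON")
  ok <- support$alt_reads >= min_alt && support$coverage >= min_cov
  if (!ok) return("DROPPED")
  if (membership == "long_only") "LR_ORIGIN" else "ILMN_ORIGIN"
}

#' Build a two-tech truth set from two platform call sets
#'
#' @param short_vcf,long_vcf VCF paths (package dialect).
#' @param short_bam,long_bam Indexed BAMs of the respective platforms.
#' @param reference Indexed FASTA.
#' @param exclude_bed Optional BED of regions to exclude.
#' @param min_alt,min_cov Rescue thresholds.
#' @param min_baseq Minimum base quality in the pileup check.
#' @param min_mapq_short,min_mapq_long Per-platform mapping-quality filters.
#' @return List with `truth` (a sorted, deduplicated `vcf_records` frame of
#'   COMMON + rescued variants) and `report` (data.frame with chrom, pos,
#'   ref, alt, vtype, category, alt_reads, coverage).
#' @export
build_truth_set <- function(short_vcf, long_vcf, short_bam, long_bam,
                            reference, exclude_bed = NULL, min_alt = 2L,
                            min_cov = 20L, min_baseq = 10L,
                            min_mapq_short = 10L, min_mapq_long = 5L) {
  short_set <- read_vcf(short_vcf)
  long_set <- read_vcf(long_vcf)
  m <- match_callsets(short_set, long_set, reference)
  if (!is.null(exclude_bed)) {
    bed <- read_bed(exclude_bed)
    m$common <- apply_exclusions(m$common, bed)
    m$a_only <- apply_exclusions(m$a_only, bed)
    m$b_only <- apply_exclusions(m$b_only, bed)
  }
  rows <- list()
  add_row <- function(rec, category, alt_reads, coverage) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = rec$chrom, pos = rec$pos, ref = rec$ref, alt = rec$alt,
      vtype = rec$vtype, category = category,
      alt_reads = alt_reads, coverage = coverage, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(m$common))) {
    add_row(m$common[i, ], "COMMON", NA_integer_, NA_integer_)
  }
  for (i in seq_len(nrow(m$a_only))) {   # Illumina-unique: check long reads
    sup <- cross_support(long_bam, m$a_only[i, ], reference, min_baseq,
                         min_mapq_long)
    add_row(m$a_only[i, ], classify("short_only", sup, min_alt, min_cov),
            sup$alt_reads, sup$coverage)
  }
  for (i in seq_len(nrow(m$b_only))) {   # long-read-unique: check short reads
    sup <- cross_support(short_bam, m$b_only[i, ], reference, min_baseq,
                         min_mapq_short)
    add_row(m$b_only[i, ], classify("long_only", sup, min_alt, min_cov),
            sup$alt_reads, sup$coverage)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), vtype = character(0),
               category = character(0), alt_reads = integer(0),
               coverage = integer(0), stringsAsFactors = FALSE)
  report <- report[order(report$chrom, report$pos, report$ref, report$alt), ,
                   drop = FALSE]
  rownames(report) <- NULL
  keep <- report$category != "DROPPED"
  truth_rows <- report[keep, , drop = FALSE]
  key <- paste(truth_rows$chrom, truth_rows$pos, truth_rows$ref,
               truth_rows$alt)
  truth_rows <- truth_rows[!duplicated(key), , drop = FALSE]
  truth <- vcf_records(chrom = truth_rows$chrom, pos = truth_rows$pos,
                       ref = truth_rows$ref, alt = truth_rows$alt)
  list(truth = truth, report = report)
}
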