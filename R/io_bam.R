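# BAM read selection. Reads come back as a plain data.frame ("read frame"),
# one row per alignment record, in deterministic (position, name) order.

#' Load reads overlapping a genomic window
#'
#' Returns alignment records overlapping `[start, end)` (0-based half-open)
#' that pass the mapping-quality and flag filters, sorted by (start, name,
#' flag) so the result is invariant to BAM record order. Sequences are stored
#' as BAM stores them, i.e. already in reference orientation; `strand` records
#' the original strand of the read.
#'
#' @param bam_path Coordinate-sorted, indexed BAM.
#' @param chrom Contig name.
#' @param start,end 0-based half-open window.
#' @param min_mapq Minimum mapping quality (default 0).
#' @param drop_flags Character subset of
#'   `c("duplicate", "secondary", "supplementary")`: records with any of these
#'   flags set are dropped.
#' @param sample Sample tag to assign (`"tumor"` or `"normal"`); the caller
#'   decides, the file does not know.
#' @return data.frame with columns name, sequence, qual, mapq, strand, sample,
#'   chrom, start (0-based), cigar, is_duplicate, is_secondary,
#'   is_supplementary, is_proper_pair.
#' @export
load_reads <- function(bam_path, chrom, start, end, min_mapq = 0L,
                       drop_flags = c("duplicate", "secondary", "supplementary"),
                       sample = "tumor") {
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path)
  bai <- paste0(bam_path, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam_path))) {
    stop("BAM index (.bai) not found for ", bam_path)
  }
  if (length(drop_flags)) {
    stopifnot(all(drop_flags %in% c("duplicate", "secondary", "supplementary")))
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  param <- Rsamtools::ScanBamParam(
    which = gr,
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  res <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  n <- length(res$qname)
  if (n == 0) return(empty_read_frame())
  flag <- res$flag
  df <- data.frame(
    name = res$qname,
    sequence = toupper(as.character(res$seq)),
    qual = as.character(res$qual),
    mapq = as.integer(res$mapq),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    sample = sample,
    chrom = as.character(res$rname),
    start = as.integer(res$pos) - 1L,
    cigar = as.character(res$cigar),
    is_duplicate = bitwAnd(flag, 1024L) > 0L,
    is_secondary = bitwAnd(flag, 256L) > 0L,
    is_supplementary = bitwAnd(flag, 2048L) > 0L,
    is_proper_pair = bitwAnd(flag, 2L) > 0L,
    stringsAsFactors = FALSE)
  keep <- df$mapq >= min_mapq & !is.na(df$start)
  if ("duplicate" %in% drop_flags) keep <- keep & !df$is_duplicate
  if ("secondary" %in% drop_flags) keep <- keep & !df$is_secondary
  if ("supplementary" %in% drop_flags) keep <- keep & !df$is_supplementary
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start, df$name, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @keywords internal
empty_read_frame <- function() {
  data.frame(name = character(0), sequence = character(0), qual = character(0),
             mapq = integer(0), strand = character(0), sample = character(0),
             chrom = character(0), start = integer(0), cigar = character(0),
             is_duplicate = logical(0), is_secondary = logical(0),
             is_supplementary = logical(0), is_proper_pair = logical(0),
             stringsAsFactors = FALSE)
}
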