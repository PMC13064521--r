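# Small shared helpers: sequence manipulation, Phred encoding, k-mer extraction.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (ACGTN, case-insensitive).
#' @return Character vector of reverse complements, uppercase.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

#' Phred quality string <-> integer vector
#'
#' @param q Integer vector of Phred qualities.
#' @return Single character string (Phred+33).
#' @keywords internal
phred_to_string <- function(q) {
  intToUtf8(pmin(pmax(q, 0L), 93L) + 33L)
}

#' @rdname phred_to_string
#' @param s Phred+33 quality string.
#' @keywords internal
string_to_phred <- function(s) {
  utf8ToInt(s) - 33L
}

#' Phred quality corresponding to an error rate, capped at Q60
#' @keywords internal
error_rate_to_q <- function(error_rate) {
  if (error_rate <= 0) return(60L)
  as.integer(min(60, round(-10 * log10(error_rate))))
}

#' All k-mers of equal-length strings
#'
#' Vectorized forward-strand k-mer extraction.
#'
#' @param seqs Character vector of sequences.
#' @param k K-mer length.
#' @return Character vector of k-mers, sequence-major order; sequences shorter
#'   than `k` contribute none.
#' @keywords internal
kmerize <- function(seqs, k) {
  if (length(seqs) == 0) return(character(0))
  lens <- nchar(seqs)
  keep <- lens >= k
  if (!any(keep)) return(character(0))
  seqs <- seqs[keep]
  lens <- lens[keep]
  nk <- lens - k + 1L
  starts <- sequence(nk)
  stringi::stri_sub(rep(seqs, nk), from = starts, length = k)
}

#' Split read sequences at low-quality bases
#'
#' Bases with quality below `min_base_q` break a read into fragments; only
#' fragments of length >= k contribute k-mers.
#' @keywords internal
split_by_quality <- function(seqs, quals, min_base_q, k) {
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    q <- string_to_phred(quals[i])
    bad <- which(q < min_base_q)
    if (length(bad) == 0) {
      out[[i]] <- seqs[i]
      next
    }
    bounds <- c(0L, bad, nchar(seqs[i]) + 1L)
    segs <- character(0)
    for (j in seq_len(length(bounds) - 1L)) {
      s <- bounds[j] + 1L
      e <- bounds[j + 1L] - 1L
      if (e - s + 1L >= k) segs <- c(segs, substr(seqs[i], s, e))
    }
    out[[i]] <- segs
  }
  unlist(out, use.names = FALSE)
}

#' Parse a CIGAR string into operations
#' @return data.frame with columns `len` (int) and `op` (char).
#' @keywords internal
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || cigar == "") {
    return(data.frame(len = integer(0), op = character(0)))
  }
  lens <- as.integer(stringi::stri_extract_all_regex(cigar, "[0-9]+")[[1]])
  ops <- stringi::stri_extract_all_regex(cigar, "[MIDNSHP=X]")[[1]]
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

#' Build a CIGAR string from run-length operations
#' @keywords internal
make_cigar <- function(lens, ops) {
  stopifnot(length(lens) == length(ops))
  if (length(lens) == 0) return("*")
  paste0(lens, ops, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
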