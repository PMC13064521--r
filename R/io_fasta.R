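# FASTA access. All other modules read reference sequence through here.

#' Write an indexed FASTA file
#'
#' @param sequences Named character vector or DNAStringSet.
#' @param path Output FASTA path; a `.fai` index is created next to it.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(sequences, path) {
  if (is.character(sequences)) {
    stopifnot(!is.null(names(sequences)))
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  Biostrings::writeXStringSet(sequences, filepath = path)
  Rsamtools::indexFa(path)
  invisible(path)
}

#' Read a reference window from an indexed FASTA
#'
#' Coordinates are 0-based half-open, the package-wide convention.
#'
#' @param fasta_path Indexed FASTA file.
#' @param chrom Contig name.
#' @param start,end 0-based half-open window.
#' @return Uppercase sequence of length `end - start`.
#' @export
read_reference_window <- function(fasta_path, chrom, start, end) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  fa <- Rsamtools::FaFile(fasta_path)
  idx <- Rsamtools::scanFaIndex(fa)
  lens <- stats::setNames(GenomicRanges::width(idx),
                          as.character(GenomicRanges::seqnames(idx)))
  if (!chrom %in% names(lens)) {
    stop("unknown contig: ", chrom)
  }
  clen <- lens[[chrom]]
  if (!(start >= 0 && start < end && end <= clen)) {
    stop("window [", start, ",", end, ") out of bounds for ", chrom,
         " (length ", clen, ")")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  toupper(as.character(Rsamtools::scanFa(fa, gr)[[1]]))
}

#' Contig lengths of an indexed FASTA
#' @param fasta_path Indexed FASTA file.
#' @return Named integer vector of contig lengths.
#' @export
reference_lengths <- function(fasta_path) {
  idx <- Rsamtools::scanFaIndex(Rsamtools::FaFile(fasta_path))
  stats::setNames(as.integer(GenomicRanges::width(idx)),
                  as.character(GenomicRanges::seqnames(idx)))
}
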