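# Variant discovery from a partial-order alignment of the local reference and
# assembled haplotype contigs.

#' Default alignment scoring
#'
#' Match +2, mismatch -4, gap open -4, gap extend -2 (a gap of length L costs
#' 4 + 2L), global ends. Used for both POA and read realignment so contig and
#' read alignments are mutually consistent.
#' @return Named numeric vector.
#' @export
default_scoring <- function() {
  c(match = 2, mismatch = -4, gap_open = 4, gap_ext = 2)
}

#' Progressive partial-order multiple sequence alignment
#'
#' Builds a POA graph from the first sequence (the reference), then aligns
#' each further sequence to the graph by global sequence-to-graph dynamic
#' programming with affine gaps, fusing matched nodes. The MSA is read off
#' the graph's column (alignment-ring) order.
#'
#' @param sequences Named character vector; element 1 must be the reference
#'   (named `"ref"`). Contigs are added in the given order.
#' @param scoring Scoring vector as in [default_scoring()].
#' @return Object of class `poa_msa` with elements `rows` (named gapped
#'   strings), `col_to_ref_offset` (0-based offset of the reference base in
#'   each column, NA where the reference row has a gap), `graph` (node/edge
#'   structure with per-row traversals) and `scores` (alignment score of each
#'   added sequence against the graph at insertion time).
#' @export
poa_msa <- function(sequences, scoring = default_scoring()) {
  stopifnot(length(sequences) >= 1, all(nchar(sequences) > 0))
  if (is.null(names(sequences))) {
    names(sequences) <- c("ref", paste0("hap", seq_len(length(sequences) - 1)))
  }
  res <- .poa_msa_cpp(unname(sequences), scoring[["match"]],
                      scoring[["mismatch"]], abs(scoring[["gap_open"]]),
                      abs(scoring[["gap_ext"]]))
  rows <- stats::setNames(res$rows, names(sequences))
  ref_chars <- strsplit(rows[[1]], "", fixed = TRUE)[[1]]
  is_base <- ref_chars != "-"
  off <- rep(NA_integer_, length(ref_chars))
  off[is_base] <- seq_len(sum(is_base)) - 1L
  msa <- list(rows = rows, row_names = names(sequences),
              col_to_ref_offset = off,
              graph = list(node_base = res$node_base,
                           node_col = res$node_col,
                           edges = res$edges,
                           row_paths = stats::setNames(res$row_paths,
                                                       names(sequences))),
              scores = res$scores, scoring = scoring)
  class(msa) <- "poa_msa"
  msa
}

#' Extract candidate variants from an MSA
#'
#' Scans each non-reference row against the reference row; maximal runs of
#' difference columns (mismatch, reference gap or row gap) each become one
#' event, converted to anchored VCF representation. Duplicate (pos, ref, alt)
#' events from different rows are emitted once with all source rows recorded.
#' Events are *not* yet left-normalized; see [left_normalize()].
#'
#' @param msa A `poa_msa`.
#' @param chrom Contig name for the emitted variants.
#' @param window_start 0-based genomic start of the window.
#' @return data.frame of class `candidate_variants` with columns chrom, pos
#'   (1-based), ref, alt, vtype, vlen, start_col, end_col, source_rows
#'   (comma-joined row names), plus per-row allele spans in
#'   `attr(, "row_spans")` (list keyed by "pos:ref:alt" then row name:
#'   `c(start, len)` in that row's ungapped coordinates and the allele the
#'   row carries).
#' @export
call_from_msa <- function(msa, chrom, window_start) {
  rows <- msa$rows
  nref <- rows[[1]]
  refc <- strsplit(nref, "", fixed = TRUE)[[1]]
  ncol <- length(refc)
  off <- msa$col_to_ref_offset
  # column -> offset of the last reference base at or before the column
  last_off <- cummax(ifelse(is.na(off), -1L, off))
  out <- list()
  spans <- list()
  row_chars <- lapply(rows, function(r) strsplit(r, "", fixed = TRUE)[[1]])
  # per-row cumulative non-gap counts (ungapped coordinate before column i)
  row_cum <- lapply(row_chars, function(ch) cumsum(ch != "-"))
  for (ri in seq_along(rows)[-1]) {
    rc <- row_chars[[ri]]
    diffc <- rc != refc
    if (!any(diffc)) next
    runs <- rle(diffc)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      c1 <- starts[k]
      c2 <- ends[k]
      ref_seg <- paste(refc[c1:c2][refc[c1:c2] != "-"], collapse = "")
      alt_seg <- paste(rc[c1:c2][rc[c1:c2] != "-"], collapse = "")
      if (nchar(ref_seg) > 0 && nchar(alt_seg) > 0) {
        pos0 <- window_start + off[c1:c2][!is.na(off[c1:c2])][1]
        ref_allele <- ref_seg
        alt_allele <- alt_seg
      } else if (nchar(alt_seg) == 0) {           # pure deletion: anchor left
        first_off <- off[c1:c2][!is.na(off[c1:c2])][1]
        if (first_off == 0) next                   # no left anchor available
        pos0 <- window_start + first_off - 1L
        anchor <- substring(msa_ref_seq(msa), first_off, first_off)
        ref_allele <- paste0(anchor, ref_seg)
        alt_allele <- anchor
      } else {                                     # pure insertion
        prev_off <- last_off[c1]
        if (prev_off < 0) next                     # insertion before window
        pos0 <- window_start + prev_off
        anchor <- substring(msa_ref_seq(msa), prev_off + 1L, prev_off + 1L)
        ref_allele <- anchor
        alt_allele <- paste0(anchor, alt_seg)
      }
      key <- paste(pos0 + 1L, ref_allele, alt_allele, sep = ":")
      if (is.null(spans[[key]])) {
        spans[[key]] <- list()
        out[[key]] <- data.frame(
          chrom = chrom, pos = pos0 + 1L, ref = ref_allele, alt = alt_allele,
          vtype = variant_type(ref_allele, alt_allele),
          vlen = abs(nchar(alt_allele) - nchar(ref_allele)),
          start_col = c1, end_col = c2,
          source_rows = names(rows)[ri], stringsAsFactors = FALSE)
      } else {
        out[[key]]$source_rows <- paste(out[[key]]$source_rows,
                                        names(rows)[ri], sep = ",")
      }
      # allele span of this event in every row's ungapped coordinates
      if (length(spans[[key]]) == 0) {
        spans[[key]] <- lapply(seq_along(rows), function(rj) {
          chj <- row_chars[[rj]]
          st <- if (c1 > 1) row_cum[[rj]][c1 - 1L] else 0L
          len <- sum(chj[c1:c2] != "-")
          allele <- paste(chj[c1:c2][chj[c1:c2] != "-"], collapse = "")
          list(start = st, len = len, allele = allele)
        })
        names(spans[[key]]) <- names(rows)
      }
    }
  }
  if (length(out) == 0) {
    res <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      vtype = character(0), vlen = integer(0),
                      start_col = integer(0), end_col = integer(0),
                      source_rows = character(0), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$pos, res$ref, res$alt), , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "row_spans") <- spans
  class(res) <- c("candidate_variants", "data.frame")
  res
}

msa_ref_seq <- function(msa) {
  gsub("-", "", msa$rows[[1]], fixed = TRUE)
}

#' Left-normalize a variant against the window reference
#'
#' Shifts indels left while the spelled haplotype is unchanged: shared
#' suffixes are trimmed (re-anchoring on the previous reference base when an
#' allele would empty), then shared prefixes are trimmed leaving at least one
#' anchor base for indels. Idempotent.
#'
#' @param pos 1-based genomic position of the first ref base.
#' @param ref,alt Allele strings.
#' @param ref_window Window reference sequence.
#' @param window_start 0-based genomic start of `ref_window`.
#' @return List with normalized `pos`, `ref`, `alt`.
#' @export
left_normalize <- function(pos, ref, alt, ref_window, window_start) {
  rel <- pos - 1L - window_start            # 0-based offset in window
  if (rel < 0 || rel + nchar(ref) > nchar(ref_window)) {
    stop("variant outside window")
  }
  if (substring(ref_window, rel + 1L, rel + nchar(ref)) != ref) {
    stop("ref allele inconsistent with reference at pos ", pos)
  }
  r <- ref
  a <- alt
  repeat {
    changed <- FALSE
    # trim common suffix while both alleles keep >= 1 base
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substring(r, nchar(r)) == substring(a, nchar(a))) {
      r <- substring(r, 1, nchar(r) - 1L)
      a <- substring(a, 1, nchar(a) - 1L)
      changed <- TRUE
    }
    # indel left shift: common last base, one allele at the anchor
    if (nchar(r) != nchar(a) &&
        substring(r, nchar(r)) == substring(a, nchar(a)) && rel > 0) {
      prev <- substring(ref_window, rel, rel)
      r <- paste0(prev, substring(r, 1, nchar(r) - 1L))
      a <- paste0(prev, substring(a, 1, nchar(a) - 1L))
      rel <- rel - 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  # trim common prefix, keeping >= 1 base in each allele
  while (nchar(r) > 1 && nchar(a) > 1 &&
         substring(r, 1, 1) == substring(a, 1, 1)) {
    r <- substring(r, 2)
    a <- substring(a, 2)
    rel <- rel + 1L
  }
  list(pos = rel + 1L + window_start, ref = r, alt = a)
}
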