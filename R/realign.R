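# Read realignment and allele-support assignment.
#
# Every constituent read is re-aligned glocally (read fully aligned, free
# target end gaps) to the local reference and to each assembled contig.
# Alignments are ranked by gap-compressed identity then score; the winning
# target decides which allele the read supports at each variant, by exact
# sequence match over the allele span plus `min_flank` anchor bases on each
# side. A read contributes at most one allele count per variant.

#' Glocal alignment of one read against one target
#'
#' Read fully aligned, free end gaps in the target; affine gap scoring as in
#' [default_scoring()].
#'
#' @param read_sequence,target_sequence Non-empty DNA strings.
#' @param scoring Scoring vector.
#' @return List with `score`, `target_start` (0-based), `matches`,
#'   `mismatches`, `gap_opens`, `gap_bases`, `cigar`, and the per-position
#'   map `target_to_read` (read index, 1-based, for every aligned target
#'   position; NA where the target base is deleted in the read).
#' @export
align_read <- function(read_sequence, target_sequence,
                       scoring = default_scoring()) {
  stopifnot(nchar(read_sequence) > 0, nchar(target_sequence) > 0)
  aln <- align_reads_to_target(read_sequence, target_sequence, scoring)
  c(aln$stats[1, ], list(cigar = aln$cigar[1],
                         target_to_read = aln$maps[[1]]))
}

# Vectorized glocal alignment of many reads against one target.
# Returns list(stats = data.frame(score, target_start, matches, mismatches,
# gap_opens, gap_bases), cigar = character, maps = list of integer vectors:
# position j of a map = target position target_start + j - 1, value = read
# index (1-based) or NA where the target base is deleted in the read).
align_reads_to_target <- function(reads, target, scoring = default_scoring(),
                                  want_maps = TRUE) {
  res <- .glocal_align_cpp(reads, target, scoring[["match"]],
                           scoring[["mismatch"]],
                           abs(scoring[["gap_open"]]),
                           abs(scoring[["gap_ext"]]), want_maps)
  stats_df <- data.frame(score = res$score, target_start = res$target_start,
                         matches = res$matches, mismatches = res$mismatches,
                         gap_opens = res$gap_opens, gap_bases = res$gap_bases)
  list(stats = stats_df, cigar = res$cigar,
       maps = if (want_maps) res$maps else NULL)
}

#' Gap-compressed identity of an alignment
#'
#' matches / (matches + mismatches + gap_opens): each gap counts once
#' regardless of its length.
#'
#' @param alignment List with `matches`, `mismatches`, `gap_opens` (e.g. from
#'   [align_read()]).
#' @return Fraction in `[0, 1]`.
#' @export
gap_compressed_identity <- function(alignment) {
  den <- alignment$matches + alignment$mismatches + alignment$gap_opens
  if (den == 0) stop("degenerate alignment: empty denominator")
  alignment$matches / den
}

#' Assign per-variant allele support from realigned reads
#'
#' @param reads Read frame for one sample.
#' @param ref_window Local reference sequence.
#' @param contigs Named character vector of contig sequences (names matching
#'   the MSA rows, e.g. "hap1").
#' @param variants `candidate_variants` from [call_from_msa()] (with the
#'   per-row span attribute).
#' @param scoring Scoring vector.
#' @param min_flank Exact-match anchor bases required on each side of the
#'   allele (default 1).
#' @param min_identity Minimum gap-compressed identity of the winning
#'   alignment for a read to contribute at all (default 0.85). Reads that
#'   barely overlap the window have no faithful full-length alignment; this
#'   filter keeps their unreliable placements out of the counts.
#' @return data.frame, one row per variant: ref_fwd, ref_rev, alt_fwd,
#'   alt_rev, depth, min-based alt/ref base qualities and mapping qualities
#'   (comma-joined lists plus means).
#' @export
assign_allele_support <- function(reads, ref_window, contigs, variants,
                                  scoring = default_scoring(),
                                  min_flank = 1L, min_identity = 0.85) {
  targets <- c(ref = unname(ref_window), contigs)
  nv <- nrow(variants)
  sup <- data.frame(ref_fwd = integer(nv), ref_rev = integer(nv),
                    alt_fwd = integer(nv), alt_rev = integer(nv),
                    depth = integer(nv))
  qlists <- replicate(nv, list(alt_bq = integer(0), alt_mq = integer(0),
                               ref_bq = integer(0), ref_mq = integer(0)),
                      simplify = FALSE)
  if (nrow(reads) == 0 || nv == 0) {
    return(finish_support(sup, qlists))
  }
  spans <- attr(variants, "row_spans")
  aln <- lapply(targets, function(t)
    align_reads_to_target(reads$sequence, t, scoring))
  gci <- vapply(aln, function(a) {
    a$stats$matches /
      pmax(a$stats$matches + a$stats$mismatches + a$stats$gap_opens, 1L)
  }, numeric(nrow(reads)))
  gci <- matrix(gci, nrow = nrow(reads))
  scr <- vapply(aln, function(a) a$stats$score, numeric(nrow(reads)))
  scr <- matrix(scr, nrow = nrow(reads))
  tnames <- names(targets)
  quals <- lapply(reads$qual, string_to_phred)
  for (ri in seq_len(nrow(reads))) {
    # rank targets: gap-compressed identity desc, score desc, name asc
    o <- order(-gci[ri, ], -scr[ri, ], tnames)
    best <- o[1]
    if (gci[ri, best] < min_identity) next
    tie <- which(gci[ri, ] == gci[ri, best] & scr[ri, ] == scr[ri, best])
    tie_names <- tnames[tie]
    tname <- tnames[best]
    map <- aln[[best]]$maps[[ri]]
    t0 <- aln[[best]]$stats$target_start[ri]
    tend <- t0 + length(map)               # aligned target span [t0, tend)
    is_fwd <- reads$strand[ri] == "+"
    for (vi in seq_len(nv)) {
      key <- paste(variants$pos[vi], variants$ref[vi], variants$alt[vi],
                   sep = ":")
      sp <- spans[[key]][[tname]]
      if (is.null(sp)) next
      locus_s <- sp$start                  # 0-based on target
      locus_e <- sp$start + max(sp$len, 1L)
      if (t0 <= locus_s && tend >= locus_e) {
        sup$depth[vi] <- sup$depth[vi] + 1L
      } else {
        next
      }
      # the read is uninformative for this variant when its equally-best
      # targets disagree on the allele carried at the locus
      if (length(tie_names) > 1) {
        tie_alleles <- vapply(tie_names, function(tn) {
          s <- spans[[key]][[tn]]
          if (is.null(s)) NA_character_ else s$allele
        }, character(1))
        if (length(unique(tie_alleles[!is.na(tie_alleles)])) > 1) next
      }
      a <- locus_s - min_flank             # inclusive flank positions
      b <- sp$start + sp$len + min_flank - 1L
      if (a < t0 || b >= tend) next
      ra <- map[a - t0 + 1L]
      rb <- map[b - t0 + 1L]
      if (is.na(ra) || is.na(rb)) next
      read_sub <- substring(reads$sequence[ri], ra, rb)
      target_sub <- substring(targets[[best]], a + 1L, b + 1L)
      if (read_sub != target_sub) next
      allele <- sp$allele
      vkey <- variants[vi, ]
      refsp <- spans[[key]][["ref"]]
      is_ref_allele <- identical(allele, refsp$allele)
      is_alt_allele <- !is_ref_allele &&
        identical(allele, alt_span_allele(spans[[key]], vkey))
      bq <- min(quals[[ri]][ra:rb])
      mq <- reads$mapq[ri]
      if (is_ref_allele) {
        if (is_fwd) sup$ref_fwd[vi] <- sup$ref_fwd[vi] + 1L
        else sup$ref_rev[vi] <- sup$ref_rev[vi] + 1L
        qlists[[vi]]$ref_bq <- c(qlists[[vi]]$ref_bq, bq)
        qlists[[vi]]$ref_mq <- c(qlists[[vi]]$ref_mq, mq)
      } else if (is_alt_allele) {
        if (is_fwd) sup$alt_fwd[vi] <- sup$alt_fwd[vi] + 1L
        else sup$alt_rev[vi] <- sup$alt_rev[vi] + 1L
        qlists[[vi]]$alt_bq <- c(qlists[[vi]]$alt_bq, bq)
        qlists[[vi]]$alt_mq <- c(qlists[[vi]]$alt_mq, mq)
      }
    }
  }
  finish_support(sup, qlists)
}

# the alt allele as spelled in any row that carries it
alt_span_allele <- function(span_list, variant) {
  rows <- strsplit(variant$source_rows, ",", fixed = TRUE)[[1]]
  span_list[[rows[1]]]$allele
}

finish_support <- function(sup, qlists) {
  sup$mean_alt_baseq <- vapply(qlists, function(q) {
    if (length(q$alt_bq)) mean(q$alt_bq) else 0
  }, numeric(1))
  sup$mean_alt_mapq <- vapply(qlists, function(q) {
    if (length(q$alt_mq)) mean(q$alt_mq) else 0
  }, numeric(1))
  sup$mean_ref_baseq <- vapply(qlists, function(q) {
    if (length(q$ref_bq)) mean(q$ref_bq) else 0
  }, numeric(1))
  sup$mean_ref_mapq <- vapply(qlists, function(q) {
    if (length(q$ref_mq)) mean(q$ref_mq) else 0
  }, numeric(1))
  stopifnot(all(sup$ref_fwd + sup$ref_rev + sup$alt_fwd + sup$alt_rev <=
                  sup$depth))
  sup
}

#' Genotype one sample at one variant
#'
#' Maximum binomial likelihood over allele fractions e (hom ref), 0.5 (het),
#' 1-e (hom alt); `./.` when no informative reads.
#'
#' @param ref_count,alt_count Informative read counts.
#' @param error_rate Sequencing error rate e (default 0.001).
#' @return List with `gt` in `c("0/0","0/1","1/1","./.")` and `vaf`.
#' @export
genotype_sample <- function(ref_count, alt_count, error_rate = 0.001) {
  n <- ref_count + alt_count
  if (n == 0) return(list(gt = "./.", vaf = NA_real_))
  ll <- c(`0/0` = stats::dbinom(alt_count, n, error_rate, log = TRUE),
          `0/1` = stats::dbinom(alt_count, n, 0.5, log = TRUE),
          `1/1` = stats::dbinom(alt_count, n, 1 - error_rate, log = TRUE))
  list(gt = names(which.max(ll)), vaf = alt_count / n)
}
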