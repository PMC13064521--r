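# Top-level tumor/normal somatic calling pipeline.

#' Call somatic variants on a tumor/normal pair
#'
#' Tiles the reference (or a region) into overlapping windows, runs per-window
#' joint assembly / POA variant discovery / realignment genotyping, merges
#' window results deterministically, optionally scores candidates with a
#' boosting model, and labels FILTER: PASS iff the candidate has a somatic
#' genotype configuration (tumor carries the alt allele, normal is 0/0) and,
#' when a model is given, its somatic probability reaches the type-specific
#' threshold; everything else is LowScore.
#'
#' Windows are independent work units: the result is byte-identical for any
#' `threads` value (worker partitioning only changes processing order).
#'
#' @param tumor_bam,normal_bam Indexed BAM paths.
#' @param reference Indexed FASTA path.
#' @param region Optional "chrom:beg-end" (1-based inclusive) restriction.
#' @param bed,exclude_bed Optional BED paths: windows are restricted to
#'   `bed` regions; variants inside `exclude_bed` are removed.
#' @param model Optional `ebm_model` for somatic scoring.
#' @param config [somagraph_config()] list.
#' @param threads Simulated worker count (determinism contract; see above).
#' @param gfa_dir Optional directory: per-window POA graphs of windows with
#'   candidates are exported as GFA.
#' @return List with `records` (a `vcf_records` frame), `candidates` (the
#'   merged candidate table with features), and `window_log` (per-window
#'   reason codes).
#' @export
call_somatic <- function(tumor_bam, normal_bam, reference, region = NULL,
                         bed = NULL, exclude_bed = NULL, model = NULL,
                         config = somagraph_config(), threads = 1L,
                         gfa_dir = NULL) {
  lens <- reference_lengths(reference)
  if (!is.null(region)) {
    m <- stringi::stri_match_first_regex(region,
                                         "^([^:]+):([0-9]+)-([0-9]+)$")
    if (is.na(m[1, 1])) stop("bad region string: ", region)
    reg <- list(chrom = m[1, 2], start = as.integer(m[1, 3]) - 1L,
                end = as.integer(m[1, 4]))
  } else {
    reg <- NULL
  }
  windows <- tile_genome(lens, config$window_size, config$overlap)
  if (!is.null(reg)) {
    windows <- windows[windows$chrom == reg$chrom & windows$end > reg$start &
                         windows$start < reg$end, , drop = FALSE]
  }
  if (!is.null(bed)) {
    inc <- read_bed(bed)
    keep <- vapply(seq_len(nrow(windows)), function(i) {
      any(inc$chrom == windows$chrom[i] & inc$end > windows$start[i] &
            inc$start < windows$end[i])
    }, logical(1))
    windows <- windows[keep, , drop = FALSE]
  }
  # simulated multi-worker scheduling: workers take windows round-robin;
  # results are merged by window index, so the output is order-invariant
  worker_order <- unlist(lapply(seq_len(max(1L, threads)), function(w) {
    which((seq_len(nrow(windows)) - 1L) %% max(1L, threads) == w - 1L)
  }))
  results <- vector("list", nrow(windows))
  log <- data.frame(index = windows$index, chrom = windows$chrom,
                    start = windows$start, end = windows$end,
                    reason = NA_character_, n_variants = 0L,
                    stringsAsFactors = FALSE)
  for (wi in worker_order) {
    w <- windows[wi, ]
    res <- process_window(w, tumor_bam, normal_bam, reference, lens, config,
                          gfa_dir)
    # score inside the window so merging can keep the higher-scored copy
    results[[wi]] <- score_candidates(res$variants, model, config)
    log$reason[log$index == w$index] <- res$reason %||% "called"
    log$n_variants[log$index == w$index] <- nrow(res$variants)
  }
  merged <- merge_windows(results)
  if (!is.null(exclude_bed)) {
    merged <- apply_exclusions(merged, read_bed(exclude_bed))
  }
  records <- candidates_to_records(merged)
  list(records = records, candidates = merged, window_log = log)
}

process_window <- function(w, tumor_bam, normal_bam, reference, lens, config,
                           gfa_dir = NULL) {
  ref_window <- read_reference_window(reference, w$chrom, w$start, w$end)
  # expanded context so read overhangs are not counted as novel sequence
  pad <- 200L
  ctx_start <- max(0L, w$start - pad)
  ctx_end <- min(lens[[w$chrom]], w$end + pad)
  ref_context <- read_reference_window(reference, w$chrom, ctx_start, ctx_end)
  tr_all <- load_reads(tumor_bam, w$chrom, w$start, w$end, min_mapq = 0L,
                       drop_flags = character(0), sample = "tumor")
  nr_all <- load_reads(normal_bam, w$chrom, w$start, w$end, min_mapq = 0L,
                       drop_flags = character(0), sample = "normal")
  pct_hq <- function(df) {
    if (nrow(df) == 0) return(100)
    hq <- df$mapq >= config$hq_mapq & !df$is_duplicate & !df$is_secondary &
      !df$is_supplementary
    100 * sum(hq) / nrow(df)
  }
  filt <- function(df) {
    keep <- df$mapq >= config$min_mapq
    if ("duplicate" %in% config$drop_flags) keep <- keep & !df$is_duplicate
    if ("secondary" %in% config$drop_flags) keep <- keep & !df$is_secondary
    if ("supplementary" %in% config$drop_flags) {
      keep <- keep & !df$is_supplementary
    }
    df[keep, , drop = FALSE]
  }
  res <- call_window(w, filt(tr_all), filt(nr_all), ref_window, config,
                     pct_hq_tumor = pct_hq(tr_all),
                     pct_hq_normal = pct_hq(nr_all),
                     ref_context = ref_context)
  if (!is.null(gfa_dir) && !is.null(res$msa) && nrow(res$variants) > 0) {
    dir.create(gfa_dir, showWarnings = FALSE, recursive = TRUE)
    write_gfa(msa_to_gfa(res$msa),
              file.path(gfa_dir, sprintf("window_%05d.gfa", w$index)))
  }
  res
}

# attach somatic scores and FILTER labels
score_candidates <- function(cands, model, config) {
  n <- nrow(cands)
  if (n == 0) {
    cands$score <- numeric(0)
    cands$filter <- character(0)
    return(cands)
  }
  somatic_config <- cands$gt_tumor %in% c("0/1", "1/1") &
    cands$gt_normal == "0/0"
  if (!is.null(model)) {
    feats <- extract_features(cands)
    cands$score <- as.numeric(sprintf("%.6g", score_ebm(model, feats)))
    pass_score <- vapply(seq_len(n), function(i) {
      apply_threshold(cands$score[i], cands$vtype[i],
                      c(SNV = config$threshold_snv,
                        INDEL = config$threshold_indel)) == "PASS"
    }, logical(1))
  } else {
    cands$score <- NA_real_
    pass_score <- rep(TRUE, n)
  }
  cands$filter <- ifelse(somatic_config & pass_score, "PASS", "LowScore")
  cands
}

candidates_to_records <- function(cands) {
  vcf_records(
    chrom = cands$chrom, pos = cands$pos, ref = cands$ref, alt = cands$alt,
    filter = cands$filter, score = cands$score,
    gt_normal = cands$gt_normal,
    ad_ref_normal = cands$ref_fwd_normal + cands$ref_rev_normal,
    ad_alt_normal = cands$alt_fwd_normal + cands$alt_rev_normal,
    dp_normal = cands$depth_normal,
    gt_tumor = cands$gt_tumor,
    ad_ref_tumor = cands$ref_fwd_tumor + cands$ref_rev_tumor,
    ad_alt_tumor = cands$alt_fwd_tumor + cands$alt_rev_tumor,
    dp_tumor = cands$depth_tumor)
}

#' Remove variants falling in BED regions
#'
#' A variant is removed when its 0-based position (`pos - 1`) lies inside any
#' half-open BED region.
#'
#' @param variants data.frame with chrom and pos (1-based) columns.
#' @param bed_regions data.frame from [read_bed()].
#' @return Filtered data.frame.
#' @export
apply_exclusions <- function(variants, bed_regions) {
  if (nrow(variants) == 0 || nrow(bed_regions) == 0) return(variants)
  p0 <- variants$pos - 1L
  drop <- vapply(seq_len(nrow(variants)), function(i) {
    any(bed_regions$chrom == variants$chrom[i] & bed_regions$start <= p0[i] &
          p0[i] < bed_regions$end)
  }, logical(1))
  out <- variants[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
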