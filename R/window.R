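# Window engine: genome tiling, active-region detection, per-window calling,
# deterministic merging, and the top-level tumor/normal calling pipeline.

#' Default caller configuration
#'
#' @param ... Overrides for any default (name = value).
#' @return Named list of configuration values.
#' @export
somagraph_config <- function(...) {
  cfg <- list(
    window_size = 600L, overlap = 250L,
    min_mapq = 10L,
    drop_flags = c("duplicate", "secondary", "supplementary"),
    k_min = 11L, k_max = 101L, k_step = 2L,
    min_base_q = 10L, min_node_cov = 2L, max_paths = 16L,
    min_active_support = 2L, min_clip = 5L,
    scoring = default_scoring(),
    min_flank = 1L, min_identity = 0.85, error_rate = 0.001,
    hq_mapq = 20L,
    threshold_snv = 0.90, threshold_indel = 0.95)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  cfg
}

#' Tile contigs into overlapping windows
#'
#' Windows start at 0, step, 2*step, ... with step = window_size - overlap;
#' the last window on a contig is clipped to the contig end. The union covers
#' every base.
#'
#' @param contig_lengths Named integer vector.
#' @param window_size,overlap Window geometry; `window_size > overlap >= 0`.
#' @return data.frame with columns chrom, start, end (0-based half-open),
#'   index (global, 1-based).
#' @export
tile_genome <- function(contig_lengths, window_size = 600L, overlap = 250L) {
  if (overlap >= window_size) stop("overlap must be smaller than window_size")
  out <- list()
  step <- window_size - overlap
  for (chrom in names(contig_lengths)) {
    len <- contig_lengths[[chrom]]
    s <- 0L
    repeat {
      e <- min(s + window_size, len)
      out[[length(out) + 1L]] <- data.frame(chrom = chrom, start = s, end = e,
                                            stringsAsFactors = FALSE)
      if (e >= len) break
      s <- s + step
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), index = integer(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df$index <- seq_len(nrow(df))
  df
}

#' Decide whether a window is active
#'
#' A window is active iff (a) at least `min_active_support` reads (from
#' either sample) contain a shared k-mer absent from the reference window,
#' or (b) any read's CIGAR contains an insertion, a deletion, or a soft clip
#' of at least `min_clip` bases.
#'
#' @param tumor_reads,normal_reads Read frames (already filtered).
#' @param ref_window Reference window sequence.
#' @param k K-mer size (odd, `k <= nchar(ref_window)`).
#' @param min_active_support Minimum reads sharing a novel k-mer.
#' @param min_clip Minimum soft-clip length that triggers activity.
#' @param ref_context Reference sequence used for the novel-k-mer test;
#'   defaults to `ref_window`. The pipeline passes the window expanded by one
#'   read length on each side so that read overhangs beyond the window edges
#'   do not look novel.
#' @return TRUE/FALSE.
#' @export
detect_active_region <- function(tumor_reads, normal_reads, ref_window, k,
                                 min_active_support = 2L, min_clip = 5L,
                                 ref_context = ref_window) {
  reads <- rbind(tumor_reads, normal_reads)
  if (nrow(reads) == 0) return(FALSE)
  cig <- reads$cigar
  for (c in cig[stringi::stri_detect_regex(cig, "[IDS]")]) {
    ops <- parse_cigar(c)
    if (any(ops$op %in% c("I", "D"))) return(TRUE)
    if (any(ops$op == "S" & ops$len >= min_clip)) return(TRUE)
  }
  ref_kmers <- unique(kmerize(ref_context, k))
  # count the number of *reads* containing each novel k-mer
  per_read <- lapply(reads$sequence, function(s) unique(kmerize(s, k)))
  km <- unlist(per_read, use.names = FALSE)
  km <- km[!km %in% ref_kmers]
  if (length(km) == 0) return(FALSE)
  any(table(km) >= min_active_support)
}

#' Call variants in one window
#'
#' Composition of assembly, MSA variant discovery, realignment genotyping and
#' feature extraction. No exception escapes: failures demote the window to
#' "no calls" with a reason code.
#'
#' @param window One row of [tile_genome()] output.
#' @param tumor_reads,normal_reads Filtered read frames.
#' @param ref_window Reference sequence of the window.
#' @param config [somagraph_config()] list.
#' @param pct_hq_tumor,pct_hq_normal Window-level percent of high-quality
#'   reads per sample (computed from unfiltered reads by the caller).
#' @return List with `variants` (data.frame of genotyped candidates with
#'   features; zero rows when inactive) , `reason` (NULL or one of "no_k",
#'   "too_many_paths", "no_contigs", "inactive"), and `msa` (the `poa_msa`
#'   or NULL) for GFA export.
#' @export
call_window <- function(window, tumor_reads, normal_reads, ref_window, config,
                        pct_hq_tumor = 100, pct_hq_normal = 100,
                        ref_context = ref_window) {
  empty <- list(variants = empty_candidates(), reason = NULL, msa = NULL)
  res <- tryCatch({
    k <- select_k(ref_window, config$k_min, config$k_max, config$k_step)
    if (!detect_active_region(tumor_reads, normal_reads, ref_window, k,
                              config$min_active_support, config$min_clip,
                              ref_context = ref_context)) {
      empty$reason <- "inactive"
      return(empty)
    }
    # assemble; if path extraction runs into graph cycles (a k-mer repeat in
    # the variant haplotype), retry at larger k until the graph is repeat-free
    ka <- k
    repeat {
      g <- build_graph(tumor_reads, normal_reads, ref_window, ka,
                       config$min_base_q)
      g <- clean_graph(g, config$min_node_cov, max_tip_len = ka)
      paths <- enumerate_paths(g, config$max_paths)
      if ((attr(paths, "n_cyclic") %||% 0L) == 0L ||
          ka + 10L > config$k_max) break
      ka <- ka + 10L
    }
    contigs <- vapply(paths, `[[`, character(1), "contig")
    sup <- vapply(paths, `[[`, numeric(1), "min_edge_support")
    keep <- contigs != ref_window
    contigs <- contigs[keep]
    sup <- sup[keep]
    if (length(contigs) == 0) {
      empty$reason <- "no_contigs"
      return(empty)
    }
    # contig addition order: descending support, ties by name
    o <- order(-sup, seq_along(contigs))
    contigs <- contigs[o]
    names(contigs) <- paste0("hap", seq_along(contigs))
    msa <- poa_msa(c(ref = unname(ref_window), contigs), config$scoring)
    cands <- call_from_msa(msa, window$chrom, window$start)
    if (nrow(cands) == 0) {
      empty$reason <- "no_contigs"
      empty$msa <- msa
      return(empty)
    }
    sup_t <- assign_allele_support(tumor_reads, ref_window, contigs, cands,
                                   config$scoring, config$min_flank,
                                   config$min_identity)
    sup_n <- assign_allele_support(normal_reads, ref_window, contigs, cands,
                                   config$scoring, config$min_flank,
                                   config$min_identity)
    vars <- genotype_candidates(cands, sup_t, sup_n, ref_window,
                                window$start, config)
    vars$window_index <- window$index
    vars$pct_hq_tumor <- pct_hq_tumor
    vars$pct_hq_normal <- pct_hq_normal
    list(variants = vars, reason = NULL, msa = msa)
  },
  no_usable_k = function(e) { empty$reason <- "no_k"; empty },
  too_many_paths = function(e) { empty$reason <- "too_many_paths"; empty })
  res
}

empty_candidates <- function() {
  df <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                   alt = character(0), vtype = character(0), vlen = integer(0),
                   stringsAsFactors = FALSE)
  for (col in c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev", "depth")) {
    df[[paste0(col, "_tumor")]] <- integer(0)
    df[[paste0(col, "_normal")]] <- integer(0)
  }
  for (col in c("mean_alt_baseq", "mean_alt_mapq")) {
    df[[paste0(col, "_tumor")]] <- numeric(0)
    df[[paste0(col, "_normal")]] <- numeric(0)
  }
  df$gt_tumor <- character(0)
  df$gt_normal <- character(0)
  df$vaf_tumor <- numeric(0)
  df$vaf_normal <- numeric(0)
  df$window_index <- integer(0)
  df$pct_hq_tumor <- numeric(0)
  df$pct_hq_normal <- numeric(0)
  df$score <- numeric(0)
  df$filter <- character(0)
  df
}

# left-normalize candidates and attach genotypes + support columns
genotype_candidates <- function(cands, sup_t, sup_n, ref_window, window_start,
                                config) {
  n <- nrow(cands)
  norm <- lapply(seq_len(n), function(i) {
    left_normalize(cands$pos[i], cands$ref[i], cands$alt[i], ref_window,
                   window_start)
  })
  df <- data.frame(
    chrom = cands$chrom,
    pos = vapply(norm, `[[`, integer(1), "pos"),
    ref = vapply(norm, `[[`, character(1), "ref"),
    alt = vapply(norm, `[[`, character(1), "alt"),
    stringsAsFactors = FALSE)
  df$vtype <- variant_type(df$ref, df$alt)
  df$vlen <- abs(nchar(df$alt) - nchar(df$ref))
  for (side in c("tumor", "normal")) {
    s <- if (side == "tumor") sup_t else sup_n
    for (col in c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev", "depth",
                  "mean_alt_baseq", "mean_alt_mapq")) {
      df[[paste0(col, "_", side)]] <- s[[col]]
    }
  }
  gts_t <- lapply(seq_len(n), function(i) {
    genotype_sample(sup_t$ref_fwd[i] + sup_t$ref_rev[i],
                    sup_t$alt_fwd[i] + sup_t$alt_rev[i], config$error_rate)
  })
  gts_n <- lapply(seq_len(n), function(i) {
    genotype_sample(sup_n$ref_fwd[i] + sup_n$ref_rev[i],
                    sup_n$alt_fwd[i] + sup_n$alt_rev[i], config$error_rate)
  })
  df$gt_tumor <- vapply(gts_t, `[[`, character(1), "gt")
  df$gt_normal <- vapply(gts_n, `[[`, character(1), "gt")
  df$vaf_tumor <- vapply(gts_t, function(g) g$vaf %||% NA_real_, numeric(1))
  df$vaf_normal <- vapply(gts_n, function(g) g$vaf %||% NA_real_, numeric(1))
  # duplicates can arise when two MSA events normalize to the same variant
  key <- paste(df$chrom, df$pos, df$ref, df$alt)
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Merge per-window results into a deduplicated sorted variant table
#'
#' Variants identical on (chrom, pos, ref, alt) are merged keeping the copy
#' with the higher somatic score (ties and missing scores: lower window
#' index). Output sorted by (chrom, pos, ref, alt).
#'
#' @param per_window_results List of candidate data.frames (each tagged with
#'   `window_index`).
#' @return Single merged data.frame.
#' @export
merge_windows <- function(per_window_results) {
  per_window_results <- Filter(function(x) !is.null(x) && nrow(x) > 0,
                               per_window_results)
  if (length(per_window_results) == 0) return(empty_candidates())
  all <- do.call(rbind, per_window_results)
  score <- if ("score" %in% names(all)) all$score else rep(NA_real_, nrow(all))
  score[is.na(score)] <- -Inf
  o <- order(all$chrom, all$pos, all$ref, all$alt, -score, all$window_index)
  all <- all[o, , drop = FALSE]
  key <- paste(all$chrom, all$pos, all$ref, all$alt)
  all <- all[!duplicated(key), , drop = FALSE]
  rownames(all) <- NULL
  all
}
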