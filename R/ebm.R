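# Glass-box somatic scoring: a cyclic additive boosting classifier.
#
# Each feature gets a binned additive shape function; training cycles through
# the features in a fixed order, fitting one depth-1 split per feature per
# round on the logistic-loss gradient residual (Newton leaf values), scaled
# by the learning rate. Updates that would increase the training loss are
# halved (deterministically, up to 20 times) before being applied, so the
# training loss is non-increasing by construction. Shapes are centered to
# mean zero over the training distribution with the means folded into the
# intercept, and predictions decompose exactly as
#   logit(p) = intercept + sum_f shape_f(x_f).

EBM_FEATURES <- c(
  "pct_hq_reads_tumor", "pct_hq_reads_normal", "vtype_code", "length",
  "depth_tumor", "depth_normal", "abs_vaf_diff",
  "alt_count_tumor", "alt_count_normal", "ref_count_tumor",
  "ref_count_normal", "strand_bias_tumor", "strand_bias_normal",
  "mean_alt_baseq_tumor", "mean_alt_mapq_tumor",
  "mean_alt_baseq_normal", "mean_alt_mapq_normal")

#' Extract the somatic-model feature matrix from a candidate table
#'
#' Window-level (percent high-quality reads per sample), variant-level (type,
#' length, depths, absolute tumor-normal VAF difference) and allele-level
#' (allele counts, strand bias, base and mapping quality) features. VAF with
#' a zero denominator is 0; strand bias is min(fwd, rev)/(fwd + rev) over alt
#' reads (0.5 = balanced, 0 = none or fully one-stranded).
#'
#' @param cands Candidate data.frame from the calling pipeline.
#' @return Numeric matrix, one row per candidate, columns `EBM_FEATURES`.
#' @export
extract_features <- function(cands) {
  n <- nrow(cands)
  vaf <- function(alt, ref) ifelse(alt + ref > 0, alt / (alt + ref), 0)
  sb <- function(fwd, rev) ifelse(fwd + rev > 0,
                                  pmin(fwd, rev) / (fwd + rev), 0)
  alt_t <- cands$alt_fwd_tumor + cands$alt_rev_tumor
  alt_n <- cands$alt_fwd_normal + cands$alt_rev_normal
  ref_t <- cands$ref_fwd_tumor + cands$ref_rev_tumor
  ref_n <- cands$ref_fwd_normal + cands$ref_rev_normal
  m <- cbind(
    pct_hq_reads_tumor = cands$pct_hq_tumor,
    pct_hq_reads_normal = cands$pct_hq_normal,
    vtype_code = match(cands$vtype, c("SNV", "INS", "DEL", "MNV")) - 1,
    length = cands$vlen,
    depth_tumor = cands$depth_tumor,
    depth_normal = cands$depth_normal,
    abs_vaf_diff = abs(vaf(alt_t, ref_t) - vaf(alt_n, ref_n)),
    alt_count_tumor = alt_t,
    alt_count_normal = alt_n,
    ref_count_tumor = ref_t,
    ref_count_normal = ref_n,
    strand_bias_tumor = sb(cands$alt_fwd_tumor, cands$alt_rev_tumor),
    strand_bias_normal = sb(cands$alt_fwd_normal, cands$alt_rev_normal),
    mean_alt_baseq_tumor = cands$mean_alt_baseq_tumor,
    mean_alt_mapq_tumor = cands$mean_alt_mapq_tumor,
    mean_alt_baseq_normal = cands$mean_alt_baseq_normal,
    mean_alt_mapq_normal = cands$mean_alt_mapq_normal)
  matrix(as.numeric(m), nrow = n, dimnames = list(NULL, colnames(m)))
}

#' Random under-sampling of the majority class
#'
#' Keeps all positives and at most `neg_per_pos` negatives per positive,
#' sampled uniformly without replacement; deterministic per seed.
#'
#' @param labels Logical or 0/1 vector.
#' @param neg_per_pos Target negatives per positive (default 30).
#' @param seed Integer seed.
#' @return Sorted integer indices of the retained examples.
#' @export
undersample <- function(labels, neg_per_pos = 30L, seed = 1L) {
  stopifnot(neg_per_pos >= 1)
  y <- as.logical(labels)
  pos <- which(y)
  neg <- which(!y)
  if (length(pos) == 0) stop("no positive examples")
  n_keep <- min(length(neg), neg_per_pos * length(pos))
  kept_neg <- with_seed_local(seed, sort(sample(neg, n_keep)))
  sort(c(pos, kept_neg))
}

bin_feature <- function(x, max_bins) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = max_bins + 1),
                               names = FALSE, type = 7))
  edges <- qs[-c(1, length(qs))]            # interior cut points
  edges <- unique(edges)
  list(edges = edges, nbin = length(edges) + 1L)
}

bin_index <- function(x, edges) {
  findInterval(x, edges, left.open = TRUE) + 1L
}

logloss <- function(y, eta) {
  p <- stats::plogis(eta)
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

#' Train the cyclic additive boosting model
#'
#' @param features Numeric matrix (rows = examples, named columns).
#' @param labels 0/1 or logical vector.
#' @param rounds Boosting rounds (default 500).
#' @param learning_rate Shrinkage (default 0.1).
#' @param max_bins Maximum quantile bins per feature (default 64).
#' @param seed Recorded in metadata (training itself is deterministic).
#' @param thresholds Named PASS thresholds (`SNV`, `INDEL`).
#' @return Object of class `ebm_model`.
#' @export
train_ebm <- function(features, labels, rounds = 500L, learning_rate = 0.1,
                      max_bins = 64L, seed = 1L,
                      thresholds = c(SNV = 0.90, INDEL = 0.95)) {
  y <- as.numeric(as.logical(labels))
  stopifnot(ncol(features) >= 1)
  if (length(unique(y)) < 2) stop("need both classes present to train")
  fn <- colnames(features)
  stopifnot(!is.null(fn))
  n <- length(y)
  bins <- lapply(seq_along(fn), function(j) bin_feature(features[, j],
                                                        max_bins))
  names(bins) <- fn
  bidx <- vapply(seq_along(fn), function(j)
    bin_index(features[, j], bins[[j]]$edges), integer(n))
  bidx <- matrix(bidx, nrow = n)
  base <- min(max(mean(y), 1e-6), 1 - 1e-6)
  intercept <- stats::qlogis(base)
  shapes <- lapply(bins, function(b) numeric(b$nbin))
  eta <- rep(intercept, n)
  loss <- logloss(y, eta)
  loss_trace <- numeric(rounds)
  for (r in seq_len(rounds)) {
    for (j in seq_along(fn)) {
      nb <- bins[[j]]$nbin
      if (nb < 2) next
      b <- bidx[, j]
      p <- stats::plogis(eta)
      g <- y - p
      h <- pmax(p * (1 - p), 1e-12)
      gs <- numeric(nb)
      hs <- numeric(nb)
      agg <- rowsum(cbind(g, h), b)
      idx <- as.integer(rownames(agg))
      gs[idx] <- agg[, 1]
      hs[idx] <- agg[, 2]
      cg <- cumsum(gs)
      ch <- cumsum(hs)
      G <- cg[nb]
      H <- ch[nb]
      s <- seq_len(nb - 1L)
      gain <- cg[s]^2 / pmax(ch[s], 1e-12) +
        (G - cg[s])^2 / pmax(H - ch[s], 1e-12)
      best <- s[which.max(gain)]
      vl <- cg[best] / pmax(ch[best], 1e-12)
      vr <- (G - cg[best]) / pmax(H - ch[best], 1e-12)
      delta <- learning_rate * ifelse(seq_len(nb) <= best, vl, vr)
      # deterministic halving guard: never allow the training loss to rise
      for (try in 1:21) {
        eta_new <- eta + delta[b]
        loss_new <- logloss(y, eta_new)
        if (loss_new <= loss + 1e-12 || try == 21) break
        delta <- delta / 2
      }
      if (loss_new <= loss + 1e-12) {
        eta <- eta_new
        loss <- loss_new
        shapes[[j]] <- shapes[[j]] + delta
      }
    }
    loss_trace[r] <- loss
  }
  # center shapes over the training distribution; fold means into intercept
  for (j in seq_along(fn)) {
    mu <- mean(shapes[[j]][bidx[, j]])
    shapes[[j]] <- shapes[[j]] - mu
    intercept <- intercept + mu
  }
  model <- list(version = 1L, intercept = intercept, feature_names = fn,
                bin_edges = lapply(bins, `[[`, "edges"), shapes = shapes,
                thresholds = thresholds,
                metadata = list(rounds = rounds,
                                learning_rate = learning_rate,
                                max_bins = max_bins, seed = seed,
                                n_train = n, base_rate = mean(y),
                                final_loss = loss),
                loss_trace = loss_trace)
  class(model) <- "ebm_model"
  model
}

feature_row_matrix <- function(model, features) {
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, names(features)))
  }
  missing <- setdiff(model$feature_names, colnames(features))
  if (length(missing)) stop("unknown/missing feature: ", missing[1])
  features[, model$feature_names, drop = FALSE]
}

#' Additive contributions of each feature for given inputs
#'
#' `intercept + rowSums(contributions)` equals `qlogis(score)` exactly (the
#' same arithmetic path is used for scoring).
#'
#' @param model An `ebm_model`.
#' @param features Named numeric vector or matrix.
#' @return List with `intercept` and `contributions` (matrix).
#' @export
explain_ebm <- function(model, features) {
  x <- feature_row_matrix(model, features)
  contrib <- vapply(seq_along(model$feature_names), function(j) {
    b <- bin_index(x[, j], model$bin_edges[[j]])
    model$shapes[[j]][b]
  }, numeric(nrow(x)))
  contrib <- matrix(contrib, nrow = nrow(x),
                    dimnames = list(NULL, model$feature_names))
  list(intercept = model$intercept, contributions = contrib)
}

#' Somatic probability of candidates under the model
#'
#' @param model An `ebm_model`.
#' @param features Named numeric vector or matrix.
#' @return Probabilities in `[0, 1]`.
#' @export
score_ebm <- function(model, features) {
  ex <- explain_ebm(model, features)
  stats::plogis(ex$intercept + rowSums(ex$contributions))
}

#' PASS / LowScore label for a scored variant
#'
#' PASS iff probability >= 0.90 for SNV/MNV and >= 0.95 for INS/DEL
#' (boundaries inclusive); thresholds are overridable.
#'
#' @param probability Somatic probability in `[0, 1]`.
#' @param vtype One of "SNV", "INS", "DEL", "MNV".
#' @param thresholds Named vector with `SNV` and `INDEL` entries.
#' @return `"PASS"` or `"LowScore"`.
#' @export
apply_threshold <- function(probability, vtype,
                            thresholds = c(SNV = 0.90, INDEL = 0.95)) {
  stopifnot(probability >= 0, probability <= 1)
  thr <- if (vtype %in% c("INS", "DEL")) thresholds[["INDEL"]] else
    thresholds[["SNV"]]
  if (probability >= thr) "PASS" else "LowScore"
}

#' Label candidates against a truth set by normalized exact match
#'
#' @param cands Candidate data.frame (chrom, pos, ref, alt), left-normalized.
#' @param truth `vcf_records` truth frame (left-normalized).
#' @param somatic_only Label only somatic truth entries as positive.
#' @param holdout_chrom Optional chromosome excluded from the returned mask
#'   (for held-out evaluation).
#' @return List with `labels` (logical) and `train_mask` (logical).
#' @export
label_candidates <- function(cands, truth, somatic_only = TRUE,
                             holdout_chrom = NULL) {
  tr <- truth
  if (somatic_only && "origin" %in% names(tr) && any(!is.na(tr$origin))) {
    tr <- tr[!is.na(tr$origin) & tr$origin == "somatic", , drop = FALSE]
  }
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  labels <- key(cands) %in% key(tr)
  mask <- if (is.null(holdout_chrom)) rep(TRUE, nrow(cands)) else
    cands$chrom != holdout_chrom
  list(labels = labels, train_mask = mask)
}
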