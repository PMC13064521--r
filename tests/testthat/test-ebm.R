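# Feature extraction, under-sampling, the cyclic additive boosting model.

fake_cands <- function(alt_t, dp_t, alt_n, dp_n, vtype = "SNV",
                       alt_fwd_t = alt_t, alt_rev_t = 0L) {
  df <- somagraph:::empty_candidates()
  row <- list(chrom = "chr1", pos = 100L, ref = "A",
              alt = if (vtype == "SNV") "T" else "AT",
              vtype = vtype, vlen = if (vtype == "SNV") 0L else 1L,
              ref_fwd_tumor = dp_t - alt_t, ref_rev_tumor = 0L,
              alt_fwd_tumor = alt_fwd_t, alt_rev_tumor = alt_rev_t,
              depth_tumor = dp_t,
              ref_fwd_normal = dp_n - alt_n, ref_rev_normal = 0L,
              alt_fwd_normal = alt_n, alt_rev_normal = 0L,
              depth_normal = dp_n,
              mean_alt_baseq_tumor = 30, mean_alt_mapq_tumor = 60,
              mean_alt_baseq_normal = 0, mean_alt_mapq_normal = 0,
              gt_tumor = "0/1", gt_normal = "0/0", vaf_tumor = 0,
              vaf_normal = 0, window_index = 1L, pct_hq_tumor = 100,
              pct_hq_normal = 100, score = NA_real_, filter = "PASS")
  as.data.frame(row, stringsAsFactors = FALSE)[names(df)]
}

test_that("feature extraction computes VAF differences and strand bias", {
  f <- extract_features(fake_cands(10L, 40L, 1L, 50L))
  expect_equal(unname(f[1, "abs_vaf_diff"]), abs(10 / 40 - 1 / 50))
  expect_equal(unname(f[1, "abs_vaf_diff"]), 0.23, tolerance = 1e-12)
  # balanced strands
  f2 <- extract_features(fake_cands(10L, 40L, 0L, 50L, alt_fwd_t = 5L,
                                    alt_rev_t = 5L))
  expect_equal(unname(f2[1, "strand_bias_tumor"]), 0.5)
  # no alt reads in normal: bias 0
  expect_equal(unname(f2[1, "strand_bias_normal"]), 0)
  # zero-depth normal: VAF_N sentinel 0, diff = VAF_T
  f3 <- extract_features(fake_cands(10L, 40L, 0L, 0L))
  expect_equal(unname(f3[1, "abs_vaf_diff"]), 0.25)
  expect_equal(unname(f3[1, "vtype_code"]), 0)
  expect_equal(unname(extract_features(
    fake_cands(5L, 20L, 0L, 20L, vtype = "INS"))[1, "vtype_code"]), 1)
})

test_that("undersampling keeps all positives and the target ratio", {
  y <- c(rep(TRUE, 50), rep(FALSE, 10000))
  idx <- undersample(y, neg_per_pos = 30L, seed = 1L)
  expect_equal(sum(y[idx]), 50L)
  expect_equal(sum(!y[idx]), 1500L)
  # shortage: everything kept
  y2 <- c(rep(TRUE, 50), rep(FALSE, 1000))
  expect_length(undersample(y2, 30L, 1L), 1050L)
  # determinism
  expect_identical(undersample(y, 30L, 9L), undersample(y, 30L, 9L))
  expect_false(identical(undersample(y, 30L, 9L), undersample(y, 30L, 10L)))
  expect_error(undersample(rep(FALSE, 10), 30L, 1L), "no positive")
})

test_that("training separates signal from noise features", {
  withr::with_seed(1, {
    n <- 2000
    x <- matrix(runif(n * 9), n, dimnames = list(NULL, paste0("f", 1:9)))
    y <- as.integer(x[, 1] > 0.5)
    flip <- runif(n) < 0.05
    y[flip] <- 1L - y[flip]
    train_idx <- seq_len(1500)
    m <- train_ebm(x[train_idx, ], y[train_idx], rounds = 150)
    p <- score_ebm(m, x[-train_idx, ])
    yy <- y[-train_idx]
    # held-out AUROC > 0.95
    auc <- mean(outer(p[yy == 1], p[yy == 0], ">") +
                  0.5 * outer(p[yy == 1], p[yy == 0], "=="))
    expect_gt(auc, 0.95)
    # the informative feature has the widest shape range
    ranges <- vapply(m$shapes, function(s) diff(range(s)), numeric(1))
    expect_equal(names(which.max(ranges)), "f1")
  })
})

test_that("constant features contribute nothing", {
  withr::with_seed(2, {
    n <- 600
    x <- cbind(sig = runif(n), const = rep(3.14, n))
    y <- as.integer(x[, "sig"] > 0.4)
    m <- train_ebm(x, y, rounds = 60)
    expect_lt(diff(range(m$shapes$const)), 1e-8)
    ex <- explain_ebm(m, c(sig = 0.9, const = 3.14))
    expect_lt(abs(ex$contributions[1, "const"]), 1e-8)
  })
})

test_that("training is deterministic and its loss is non-increasing", {
  withr::with_seed(3, {
    n <- 800
    x <- cbind(a = runif(n), b = runif(n), c = rnorm(n))
    y <- as.integer(plogis(3 * x[, "a"] - 2 * x[, "b"]) > runif(n))
    m1 <- train_ebm(x, y, rounds = 80, seed = 5)
    m2 <- train_ebm(x, y, rounds = 80, seed = 5)
    expect_identical(m1$shapes, m2$shapes)
    expect_identical(m1$intercept, m2$intercept)
    expect_true(all(diff(m1$loss_trace) <= 1e-12))
    # identical bytes on disk
    d <- withr::local_tempdir()
    save_model(m1, file.path(d, "a.json"))
    save_model(m2, file.path(d, "b.json"))
    expect_identical(readLines(file.path(d, "a.json")),
                     readLines(file.path(d, "b.json")))
  })
})

test_that("explanations decompose the score exactly", {
  withr::with_seed(4, {
    n <- 500
    x <- cbind(u = runif(n), v = runif(n), w = runif(n))
    y <- as.integer(x[, "u"] + 0.3 * x[, "v"] > 0.7)
    m <- train_ebm(x, y, rounds = 60)
    xs <- cbind(u = runif(200), v = runif(200), w = runif(200))
    ex <- explain_ebm(m, xs)
    p <- score_ebm(m, xs)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(ex$intercept + rowSums(ex$contributions), qlogis(p),
                 tolerance = 1e-9)
    expect_error(score_ebm(m, c(u = 1, v = 2)), "feature")
  })
})

test_that("fitted shapes recover known additive step functions", {
  withr::with_seed(6, {
    n <- 5000
    x <- cbind(s1 = runif(n), s2 = runif(n), noise = runif(n))
    true1 <- function(z) ifelse(z > 0.6, 1.5, -0.5)
    true2 <- function(z) ifelse(z > 0.3, -1.0, 1.0)
    eta <- true1(x[, "s1"]) + true2(x[, "s2"])
    y <- as.integer(runif(n) < plogis(eta))
    m <- train_ebm(x, y, rounds = 200)
    grid <- seq(0.01, 0.99, by = 0.02)
    shape_on <- function(model, f, g) {
      b <- somagraph:::bin_index(g, model$bin_edges[[f]])
      model$shapes[[f]][b]
    }
    c1 <- cor(shape_on(m, "s1", grid), true1(grid))
    c2 <- cor(shape_on(m, "s2", grid), true2(grid))
    expect_gt(c1, 0.9)
    expect_gt(c2, 0.9)
  })
})

test_that("type-specific thresholds gate PASS labels at the boundaries", {
  expect_equal(apply_threshold(0.92, "SNV"), "PASS")
  expect_equal(apply_threshold(0.92, "DEL"), "LowScore")
  expect_equal(apply_threshold(0.95, "INS"), "PASS")
  expect_equal(apply_threshold(0.90, "SNV"), "PASS")
  expect_equal(apply_threshold(0.8999, "SNV"), "LowScore")
  expect_equal(apply_threshold(0.9499, "DEL"), "LowScore")
  expect_equal(apply_threshold(0.92, "MNV"), "PASS")   # MNV uses SNV cutoff
  # user-overridable
  expect_equal(apply_threshold(0.5, "SNV", c(SNV = 0.4, INDEL = 0.6)),
               "PASS")
})

test_that("candidate labelling matches truth by normalized identity", {
  truth <- vcf_records(chrom = "chr1", pos = 10L, ref = "A", alt = "T",
                       origin = "somatic")
  cands <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      pos = c(10L, 11L, 10L), ref = c("A", "C", "A"),
                      alt = c("T", "G", "T"), stringsAsFactors = FALSE)
  lab <- label_candidates(cands, truth)
  expect_equal(lab$labels, c(TRUE, FALSE, FALSE))
  lab2 <- label_candidates(cands, truth, holdout_chrom = "chr2")
  expect_equal(lab2$train_mask, c(TRUE, TRUE, FALSE))
})
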