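# Genome tiling, active-region detection, window merging, determinism.

test_that("tile_genome follows the stepping rule and covers every base", {
  w <- tile_genome(c(chr1 = 1000L), 600L, 250L)
  expect_equal(w$start, c(0L, 350L, 700L))
  expect_equal(w$end, c(600L, 950L, 1000L))
  # contig shorter than a window
  w2 <- tile_genome(c(chr1 = 300L), 600L, 250L)
  expect_equal(nrow(w2), 1L)
  expect_equal(c(w2$start, w2$end), c(0L, 300L))
  # no contigs
  expect_equal(nrow(tile_genome(stats::setNames(integer(0), character(0)),
                                600L, 250L)), 0L)
  expect_error(tile_genome(c(chr1 = 100L), 600L, 600L), "overlap")
  # coverage property over random contig lengths
  withr::with_seed(19, {
    for (i in 1:10) {
      len <- sample(100:5000, 1)
      w <- tile_genome(c(c1 = len), 600L, 250L)
      covered <- rep(FALSE, len)
      for (j in seq_len(nrow(w))) covered[(w$start[j] + 1):w$end[j]] <- TRUE
      expect_true(all(covered))
      # interior bases sit well inside at least one window
      interior <- rep(FALSE, len)
      for (j in seq_len(nrow(w))) {
        a <- w$start[j] + min(125, (w$end[j] - w$start[j]) %/% 2)
        b <- w$end[j] - min(125, (w$end[j] - w$start[j]) %/% 2)
        if (b > a) interior[(a + 1):b] <- TRUE
      }
      margin <- 250
      core <- seq_len(len) > margin & seq_len(len) <= len - margin
      expect_true(all(interior[core]))
    }
  })
})

test_that("active-region detection requires shared novel k-mers or indels", {
  withr::with_seed(20, {
    ref <- random_dna(300)
    k <- 11L
    none <- make_read_frame(character(0))
    # exact substrings: inactive
    subs <- vapply(c(1, 50, 120), function(s)
      substring(ref, s, s + 99), character(1))
    expect_false(detect_active_region(make_read_frame(subs), none, ref, k))
    # two tumor reads with the same SNV: active (oracle agrees)
    ch <- strsplit(ref, "")[[1]]
    ch[150] <- setdiff(c("A", "C", "G", "T"), ch[150])[1]
    mut <- paste(ch, collapse = "")
    mreads <- c(substring(mut, 100, 199), substring(mut, 120, 219))
    expect_true(novel_kmer_oracle(mreads, ref, k, 2))
    expect_true(detect_active_region(make_read_frame(mreads), none, ref, k))
    # one read with a singleton error: inactive at min_active_support = 2
    one <- make_read_frame(substring(mut, 100, 199))
    expect_false(novel_kmer_oracle(one$sequence, ref, k, 2))
    expect_false(detect_active_region(one, none, ref, k))
    # an indel CIGAR triggers activity regardless of k-mers
    indel <- make_read_frame(substring(ref, 10, 109), cigar = "50M5D50M")
    expect_true(detect_active_region(indel, none, ref, k))
    # soft clips below min_clip do not
    clip4 <- make_read_frame(substring(ref, 10, 109), cigar = "4S96M")
    expect_false(detect_active_region(clip4, none, ref, k))
    clip5 <- make_read_frame(substring(ref, 10, 109), cigar = "5S95M")
    expect_true(detect_active_region(clip5, none, ref, k))
    # empty read lists
    expect_false(detect_active_region(none, none, ref, k))
  })
})

test_that("merge_windows deduplicates by score then window index", {
  base <- function(pos, ref, alt, score, wi) {
    df <- somagraph:::empty_candidates()[0, ]
    row <- list(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                vtype = variant_type(ref, alt),
                vlen = abs(nchar(alt) - nchar(ref)))
    for (nm in names(somagraph:::empty_candidates())) {
      if (!nm %in% names(row)) row[[nm]] <- 0L
    }
    row$score <- score
    row$filter <- "PASS"
    row$window_index <- wi
    as.data.frame(row, stringsAsFactors = FALSE)
  }
  # same SNV in two windows: higher score wins
  m <- merge_windows(list(base(100L, "A", "T", 0.97, 3L),
                          base(100L, "A", "T", 0.95, 4L)))
  expect_equal(nrow(m), 1L)
  expect_equal(m$score, 0.97)
  expect_equal(m$window_index, 3L)
  # equal scores: lower window index
  m2 <- merge_windows(list(base(100L, "A", "T", 0.9, 4L),
                           base(100L, "A", "T", 0.9, 3L)))
  expect_equal(m2$window_index, 3L)
  # disjoint variants concatenate sorted
  m3 <- merge_windows(list(base(200L, "C", "G", NA_real_, 1L),
                           base(100L, "A", "T", NA_real_, 2L)))
  expect_equal(m3$pos, c(100L, 200L))
})

test_that("inactive windows yield no calls", {
  fx <- fixture_somatic(variant_specs(), seed = 40, length = 900,
                        tumor_cov = 20, normal_cov = 15)
  res <- call_somatic(fx$tumor_bam, fx$normal_bam, fx$reference)
  expect_equal(nrow(res$records), 0L)
  expect_true(all(res$window_log$reason %in% c("inactive", "no_contigs")))
})

test_that("a somatic het SNV yields exactly one candidate at the truth locus", {
  ref <- sim_reference(1200, 41)
  b <- substring(ref, 601, 601)
  a <- setdiff(c("A", "C", "G", "T"), b)[1]
  fx <- fixture_somatic(variant_specs(pos0 = 600L, ref = b, alt = a,
                                      zygosity = "het", origin = "somatic",
                                      tumor_vaf = 0.5),
                        seed = 41, length = 1200)
  res <- call_somatic(fx$tumor_bam, fx$normal_bam, fx$reference)
  expect_equal(nrow(res$records), 1L)
  expect_equal(res$records$pos, 601L)
  expect_equal(res$records$ref, b)
  expect_equal(res$records$alt, a)
  expect_equal(res$records$gt_tumor, "0/1")
  expect_equal(res$records$gt_normal, "0/0")
  expect_equal(res$records$filter, "PASS")
})

test_that("single- and multi-worker runs write byte-identical VCFs", {
  # 10-window fixture: a 4.1 kb contig with two somatic events
  ref <- sim_reference(4100, 42)
  b1 <- substring(ref, 1001, 1001)
  a1 <- setdiff(c("A", "C", "G", "T"), b1)[1]
  del <- substring(ref, 2901, 2921)
  specs <- variant_specs(pos0 = c(1000L, 2900L),
                         ref = c(b1, del),
                         alt = c(a1, substring(del, 1, 1)),
                         zygosity = "het", origin = "somatic",
                         tumor_vaf = 0.5)
  dir <- withr::local_tempdir()
  fx <- simulate_tumor_normal(specs, dir, length = 4100, seed = 42,
                              tumor_cov = 50, normal_cov = 40,
                              error_rate = 0.001)
  out <- character(3)
  for (th in 1:3) {
    res <- call_somatic(fx$tumor_bam, fx$normal_bam, fx$reference,
                        threads = th)
    p <- file.path(dir, sprintf("t%d.vcf", th))
    write_vcf(res$records, reference_name = "ref", path = p)
    out[th] <- paste(readLines(p), collapse = "\n")
  }
  expect_identical(out[1], out[2])
  expect_identical(out[1], out[3])
  expect_equal(nrow(tile_genome(c(chr1 = 4100L), 600L, 250L)), 11L)
})

test_that("region and BED restrictions and exclusions apply", {
  ref <- sim_reference(1200, 43)
  b <- substring(ref, 601, 601)
  a <- setdiff(c("A", "C", "G", "T"), b)[1]
  fx <- fixture_somatic(variant_specs(pos0 = 600L, ref = b, alt = a,
                                      zygosity = "het", origin = "somatic",
                                      tumor_vaf = 0.5),
                        seed = 43, length = 1200)
  dir <- withr::local_tempdir()
  # region away from the variant: no calls
  res0 <- call_somatic(fx$tumor_bam, fx$normal_bam, fx$reference,
                       region = "chr1:1-200")
  expect_equal(nrow(res0$records), 0L)
  # exclusion BED over the variant removes it
  bed <- file.path(dir, "x.bed")
  writeLines("chr1\t550\t650", bed)
  res1 <- call_somatic(fx$tumor_bam, fx$normal_bam, fx$reference,
                       exclude_bed = bed)
  expect_equal(nrow(res1$records), 0L)
  # half-open exclusion boundary: variant at 0-based 600 kept for end 600
  writeLines("chr1\t550\t600", bed)
  res2 <- call_somatic(fx$tumor_bam, fx$normal_bam, fx$reference,
                       exclude_bed = bed)
  expect_equal(res2$records$pos, 601L)
})
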