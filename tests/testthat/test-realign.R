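# Read realignment, gap-compressed identity, allele support, genotyping.

test_that("align_read handles exact, mismatched and gapped reads", {
  withr::with_seed(15, {
    target <- random_dna(300)
    # exact substring: all-match cigar
    read <- substring(target, 51, 150)
    a <- align_read(read, target)
    expect_equal(a$cigar, "100M")
    expect_equal(a$mismatches, 0L)
    expect_equal(a$gap_opens, 0L)
    expect_equal(a$score, 200)
    expect_equal(a$target_start, 50L)
    # one mismatch: score = 2(L-1) - 4
    ch <- strsplit(read, "")[[1]]
    ch[40] <- setdiff(c("A", "C", "G", "T"), ch[40])[1]
    a2 <- align_read(paste(ch, collapse = ""), target)
    expect_equal(a2$score, 2 * 99 - 4)
    expect_equal(a2$mismatches, 1L)
    # read spanning a 5-bp deletion: one gap open, 5 gap bases
    read3 <- paste0(substring(target, 51, 100), substring(target, 106, 155))
    a3 <- align_read(read3, target)
    expect_equal(a3$gap_opens, 1L)
    expect_equal(a3$gap_bases, 5L)
    expect_equal(a3$score, 2 * 100 - (4 + 2 * 5))
  })
})

test_that("glocal scores equal the independent alignment oracle", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                  baseOnly = TRUE)
  withr::with_seed(16, {
    for (i in 1:40) {
      n <- sample(80:300, 1)
      target <- random_dna(n)
      m <- sample(30:min(120, n), 1)
      type <- sample(1:3, 1)
      if (type == 1) {
        s <- sample(1:(n - m + 1), 1)
        read <- substring(target, s, s + m - 1)
        ch <- strsplit(read, "")[[1]]
        for (p in sample(m, sample(0:3, 1))) {
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        }
        read <- paste(ch, collapse = "")
      } else if (type == 2) {
        s <- sample(1:(n - m - 10), 1)
        read <- paste0(substring(target, s, s + m %/% 2),
                       substring(target, s + m %/% 2 + sample(2:8, 1),
                                 s + m + 5))
      } else {
        read <- random_dna(m)
      }
      mine <- align_read(read, target)$score
      orac <- as.numeric(Biostrings::score(Biostrings::pairwiseAlignment(
        read, target, type = "global-local", substitutionMatrix = mat,
        gapOpening = 4, gapExtension = 2)))
      expect_equal(mine, orac, info = paste("case", i))
    }
  })
})

test_that("gap-compressed identity counts each gap once", {
  expect_equal(gap_compressed_identity(
    list(matches = 100, mismatches = 0, gap_opens = 0)), 1.0)
  expect_equal(gap_compressed_identity(
    list(matches = 98, mismatches = 1, gap_opens = 1)), 0.98)
  expect_equal(gap_compressed_identity(
    list(matches = 98, mismatches = 1, gap_opens = 5)), 98 / 104)
  expect_error(gap_compressed_identity(
    list(matches = 0, mismatches = 0, gap_opens = 0)), "degenerate")
})

test_that("allele support assigns each read once per variant with flanks", {
  withr::with_seed(17, {
    ref_win <- random_dna(200)
    # contig with two SNVs
    ch <- strsplit(ref_win, "")[[1]]
    ch[60] <- setdiff(c("A", "C", "G", "T"), ch[60])[1]
    ch[140] <- setdiff(c("A", "C", "G", "T"), ch[140])[1]
    contig <- paste(ch, collapse = "")
    contigs <- c(hap1 = contig)
    msa <- poa_msa(c(ref = ref_win, contigs))
    vars <- call_from_msa(msa, "chr1", 0L)
    expect_equal(nrow(vars), 2L)
    # one alt read spanning both variants, one spanning the first only,
    # one ref read spanning the first
    reads <- make_read_frame(
      c(substring(contig, 40, 160),    # spans both SNVs (alt)
        substring(contig, 45, 80),     # spans first only (alt)
        substring(ref_win, 45, 80)),   # spans first only (ref)
      strand = c("+", "-", "+"))
    sup <- assign_allele_support(reads, ref_win, contigs, vars)
    # variant order follows position
    expect_equal(sup$alt_fwd + sup$alt_rev, c(2L, 1L))
    expect_equal(sup$ref_fwd + sup$ref_rev, c(1L, 0L))
    expect_equal(sup$alt_fwd, c(1L, 1L))   # strand bookkeeping
    expect_equal(sup$alt_rev, c(1L, 0L))
    expect_true(all(sup$ref_fwd + sup$ref_rev + sup$alt_fwd + sup$alt_rev <=
                      sup$depth))
    # a read ending exactly at the variant base lacks the right flank:
    # depth only
    reads2 <- make_read_frame(substring(contig, 40, 60))
    sup2 <- assign_allele_support(reads2, ref_win, contigs, vars)
    expect_equal(sup2$depth[1], 1L)
    expect_equal(sup2$alt_fwd[1] + sup2$alt_rev[1] +
                   sup2$ref_fwd[1] + sup2$ref_rev[1], 0L)
  })
})

test_that("allele counts are invariant to read order", {
  withr::with_seed(18, {
    ref_win <- random_dna(160)
    ch <- strsplit(ref_win, "")[[1]]
    ch[80] <- setdiff(c("A", "C", "G", "T"), ch[80])[1]
    contig <- paste(ch, collapse = "")
    contigs <- c(hap1 = contig)
    vars <- call_from_msa(poa_msa(c(ref = ref_win, contigs)), "chr1", 0L)
    seqs <- c(substring(contig, 50, 120), substring(ref_win, 40, 110),
              substring(contig, 60, 130), substring(ref_win, 70, 140))
    s1 <- assign_allele_support(make_read_frame(seqs), ref_win, contigs, vars)
    s2 <- assign_allele_support(make_read_frame(rev(seqs)), ref_win, contigs,
                                vars)
    expect_equal(s1$alt_fwd + s1$alt_rev, s2$alt_fwd + s2$alt_rev)
    expect_equal(s1$ref_fwd + s1$ref_rev, s2$ref_fwd + s2$ref_rev)
    expect_equal(s1$depth, s2$depth)
  })
})

test_that("genotyping maximizes the binomial likelihood", {
  # brute-force likelihood comparison oracle
  oracle <- function(ref, alt, e = 0.001) {
    n <- ref + alt
    if (n == 0) return("./.")
    ll <- c(dbinom(alt, n, e), dbinom(alt, n, 0.5), dbinom(alt, n, 1 - e))
    c("0/0", "0/1", "1/1")[which.max(ll)]
  }
  expect_equal(genotype_sample(50, 0)$gt, "0/0")
  expect_equal(genotype_sample(32, 28)$gt, oracle(32, 28))
  expect_equal(genotype_sample(32, 28)$gt, "0/1")
  expect_equal(genotype_sample(1, 59)$gt, oracle(1, 59))
  expect_equal(genotype_sample(1, 59)$gt, "1/1")
  expect_equal(genotype_sample(0, 0)$gt, "./.")
  expect_true(is.na(genotype_sample(0, 0)$vaf))
  for (alt in c(0, 3, 10, 30, 55, 60)) {
    expect_equal(genotype_sample(60 - alt, alt)$gt, oracle(60 - alt, alt),
                 info = alt)
  }
  expect_equal(genotype_sample(30, 30)$vaf, 0.5)
})

test_that("observed tumor VAF tracks the simulated VAF across seeds", {
  # pooled binomial check at modest scale: per-seed alt fractions of an
  # error-free het SNV stay within the 99% binomial band
  hits <- 0L
  n_seeds <- 12L
  for (seed in seq_len(n_seeds)) {
    ref <- sim_reference(900, seed + 100)
    b <- substring(ref, 451, 451)
    a <- setdiff(c("A", "C", "G", "T"), b)[1]
    specs <- variant_specs(pos0 = 450L, ref = b, alt = a, zygosity = "het",
                           origin = "somatic", tumor_vaf = 0.5)
    dir <- withr::local_tempdir()
    fx <- simulate_tumor_normal(specs, dir, length = 900, seed = seed + 100,
                                tumor_cov = 40, normal_cov = 20,
                                error_rate = 0)
    res <- call_somatic(fx$tumor_bam, fx$normal_bam, fx$reference)
    i <- which(res$candidates$pos == 451L)
    if (length(i) == 1) {
      alt <- res$candidates$alt_fwd_tumor[i] + res$candidates$alt_rev_tumor[i]
      refc <- res$candidates$ref_fwd_tumor[i] +
        res$candidates$ref_rev_tumor[i]
      ci <- qbinom(c(0.005, 0.995), alt + refc, 0.5)
      if (alt >= ci[1] && alt <= ci[2]) hits <- hits + 1L
    }
  }
  expect_gte(hits, n_seeds - 1L)
})
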