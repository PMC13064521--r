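# Colored de Bruijn graph assembly: k selection, construction, cleaning,
# path enumeration.

test_that("select_k picks the smallest repeat-free odd k", {
  withr::with_seed(4, {
    # random window: 11 almost surely works, verify by brute force
    ref <- random_dna(590)
    k <- select_k(ref)
    expect_equal(k, 11L)
    expect_false(anyDuplicated(somagraph:::kmerize(ref, k)) > 0)
  })
  # periodic sequence: brute-force multiplicity check says 9 is the first
  ref <- "ACGTACGTACGT"
  brute <- function(k) !anyDuplicated(somagraph:::kmerize(ref, k))
  expect_false(brute(3)); expect_false(brute(5)); expect_false(brute(7))
  expect_true(brute(9))
  expect_equal(select_k(ref, k_min = 3L, k_max = 11L, step = 2L), 9L)
  # homopolymer: no usable k
  expect_error(select_k(strrep("A", 50), k_min = 11L, k_max = 31L),
               class = "no_usable_k")
})

test_that("graph construction counts k-mers per color", {
  withr::with_seed(5, {
    ref <- random_dna(120)
    k <- select_k(ref, k_min = 11L)
    none <- make_read_frame(character(0))
    g0 <- build_graph(none, none, ref, k)
    expect_equal(nrow(g0$nodes), nchar(ref) - k + 1L)
    expect_true(all(g0$nodes$tumor == 0L & g0$nodes$normal == 0L))
    expect_true(all(g0$nodes$on_ref))
    # reads that are exact copies of the reference: same node set, counts =
    # brute-force per-k-mer occurrence counts
    tr <- make_read_frame(rep(ref, 3))
    nr <- make_read_frame(rep(ref, 2), sample = "normal")
    g1 <- build_graph(tr, nr, ref, k)
    expect_equal(sort(g1$nodes$kmer), sort(g0$nodes$kmer))
    expect_true(all(g1$nodes$tumor == 3L))
    expect_true(all(g1$nodes$normal == 2L))
    # one tumor read with a mid-window SNV adds exactly k novel tumor nodes
    mid <- 60L
    ch <- strsplit(ref, "")[[1]]
    ch[mid] <- setdiff(c("A", "C", "G", "T"), ch[mid])[1]
    mut <- paste(ch, collapse = "")
    g2 <- build_graph(make_read_frame(c(ref, mut)), none, ref, k)
    novel <- g2$nodes[!g2$nodes$on_ref, ]
    expect_equal(nrow(novel), k)
    expect_true(all(novel$tumor == 1L & novel$normal == 0L))
  })
})

test_that("low-quality bases break reads into k-mer fragments", {
  ref <- withr::with_seed(6, random_dna(80))
  k <- 11L
  rd <- make_read_frame(ref)
  # poison one central base
  q <- somagraph:::string_to_phred(rd$qual[1])
  q[40] <- 2L
  rd$qual[1] <- somagraph:::phred_to_string(q)
  g <- build_graph(rd, make_read_frame(character(0)), ref, k,
                   min_base_q = 10L)
  covered <- g$nodes$tumor > 0
  # k-mers overlapping position 40 get no read support
  expect_equal(sum(covered), (nchar(ref) - k + 1L) - k)
})

test_that("cleaning removes weak bubbles and tips but never the reference", {
  withr::with_seed(7, {
    ref <- random_dna(150)
    k <- select_k(ref, k_min = 11L)
    ch <- strsplit(ref, "")[[1]]
    ch[70] <- setdiff(c("A", "C", "G", "T"), ch[70])[1]
    mut <- paste(ch, collapse = "")
    none <- make_read_frame(character(0))
    # a single read's mismatch (count 1) forms a bubble; min_node_cov=2
    # removes it entirely
    g <- build_graph(make_read_frame(c(ref, ref, mut)), none, ref, k)
    cleaned <- clean_graph(g, min_node_cov = 2L, max_tip_len = k)
    expect_true(all(cleaned$nodes$on_ref))
    expect_equal(nrow(cleaned$nodes), nchar(ref) - k + 1L)
    # reference nodes with zero read count are protected
    g0 <- clean_graph(build_graph(none, none, ref, k), 2L, k)
    expect_equal(nrow(g0$nodes), nchar(ref) - k + 1L)
    # idempotence
    again <- clean_graph(cleaned, 2L, k)
    expect_equal(again$nodes, cleaned$nodes)
    expect_equal(again$edges, cleaned$edges)
    # monotone: cleaning never adds nodes
    expect_lte(nrow(cleaned$nodes), nrow(g$nodes))
  })
})

test_that("graph build is invariant to read input order", {
  withr::with_seed(8, {
    ref <- random_dna(150)
    k <- select_k(ref, k_min = 11L)
    reads <- vapply(1:6, function(i) {
      s <- sample(1:(nchar(ref) - 60), 1)
      substring(ref, s, s + 59)
    }, character(1))
    none <- make_read_frame(character(0))
    g1 <- build_graph(make_read_frame(reads), none, ref, k)
    g2 <- build_graph(make_read_frame(rev(reads)), none, ref, k)
    expect_equal(g1$nodes, g2$nodes)
    expect_equal(g1$edges, g2$edges)
  })
})

test_that("path enumeration recovers reference and bubble haplotypes", {
  withr::with_seed(9, {
    ref <- random_dna(150)
    k <- select_k(ref, k_min = 11L)
    none <- make_read_frame(character(0))
    # linear reference-only graph: exactly one path spelling the window
    g <- clean_graph(build_graph(none, none, ref, k), 2L, k)
    p <- enumerate_paths(g)
    expect_length(p, 1L)
    expect_equal(p[[1]]$contig, ref)
    # SNV bubble: both haplotypes, better-supported first
    ch <- strsplit(ref, "")[[1]]
    ch[75] <- setdiff(c("A", "C", "G", "T"), ch[75])[1]
    mut <- paste(ch, collapse = "")
    tr <- make_read_frame(c(rep(ref, 5), rep(mut, 3)))
    g2 <- clean_graph(build_graph(tr, none, ref, k), 2L, k)
    p2 <- enumerate_paths(g2)
    expect_length(p2, 2L)
    expect_setequal(vapply(p2, `[[`, character(1), "contig"), c(ref, mut))
    expect_equal(p2[[1]]$contig, ref)   # higher support extracted first
    # spelled reference path is exact pre- and post-cleaning
    raw <- build_graph(tr, none, ref, k)
    spell <- function(g) {
      paste0(g$ref_path[1],
             paste(substring(g$ref_path[-1], g$k, g$k), collapse = ""))
    }
    expect_equal(spell(raw), ref)
    expect_equal(spell(g2), ref)
  })
})

test_that("max_paths caps extraction and flags leftover haplotypes", {
  withr::with_seed(10, {
    ref <- random_dna(150)
    k <- select_k(ref, k_min = 11L)
    ch <- strsplit(ref, "")[[1]]
    ch[75] <- setdiff(c("A", "C", "G", "T"), ch[75])[1]
    mut <- paste(ch, collapse = "")
    tr <- make_read_frame(c(rep(ref, 5), rep(mut, 3)))
    g <- clean_graph(build_graph(tr, make_read_frame(character(0)), ref, k),
                     2L, k)
    expect_error(enumerate_paths(g, max_paths = 1L),
                 class = "too_many_paths")
  })
})

test_that("two-haplotype windows from the simulator are fully recovered", {
  fx <- fixture_somatic(local({
    ref <- sim_reference(1200, 21)
    del <- substring(ref, 601, 621)
    variant_specs(pos0 = 600L, ref = del, alt = substring(del, 1, 1),
                  zygosity = "het", origin = "somatic", tumor_vaf = 0.5)
  }), seed = 21, length = 1200)
  ref_win <- read_reference_window(fx$reference, "chr1", 350, 950)
  tr <- load_reads(fx$tumor_bam, "chr1", 350, 950, min_mapq = 10)
  nr <- load_reads(fx$normal_bam, "chr1", 350, 950, min_mapq = 10,
                   sample = "normal")
  k <- select_k(ref_win)
  g <- clean_graph(build_graph(tr, nr, ref_win, k), 2L, k)
  p <- enumerate_paths(g)
  contigs <- vapply(p, `[[`, character(1), "contig")
  # the two true local haplotypes (oracle: simulator's haplotype sequences)
  hap_alt <- vapply(fx$haplotypes$tumor, function(h)
    nchar(h$seq) < 1200, logical(1))
  true_alt <- substring(fx$haplotypes$tumor[[which(hap_alt)]]$seq,
                        351, 950 - 20)
  expect_true(ref_win %in% contigs)
  expect_true(true_alt %in% contigs)
  expect_length(contigs, 2L)
})
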