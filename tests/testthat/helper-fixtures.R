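# Shared fixtures and independent oracles, built in code at test time.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# write a hand-specified BAM: df has columns name, flag, pos0, mapq, cigar,
# seq (qual defaults to Q30)
write_tiny_bam <- function(df, chrom, chrom_len, bam_path) {
  qual <- vapply(nchar(df$seq), function(n)
    somagraph:::phred_to_string(rep(30L, n)), character(1))
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len),
    vapply(seq_len(nrow(df)), function(i) {
      paste(df$name[i], df$flag[i], chrom, df$pos0[i] + 1L, df$mapq[i],
            df$cigar[i], "*", 0, 0, df$seq[i], qual[i], sep = "\t")
    }, character(1)))
  o <- order(df$pos0)
  lines <- c(lines[1:2], lines[-(1:2)][o])
  sam <- paste0(tools::file_path_sans_ext(bam_path), ".sam")
  writeLines(lines, sam)
  Rsamtools::asBam(sam, destination = tools::file_path_sans_ext(bam_path),
                   overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  bam_path
}

# reads as a read frame directly (no BAM round trip), for unit tests
make_read_frame <- function(seqs, start0 = 0L, sample = "tumor",
                            strand = "+", mapq = 60L, cigar = NULL,
                            qual_q = 30L) {
  n <- length(seqs)
  if (n == 0) return(somagraph:::empty_read_frame())
  data.frame(
    name = sprintf("r%03d", seq_len(n)),
    sequence = seqs,
    qual = vapply(nchar(seqs), function(l)
      somagraph:::phred_to_string(rep(qual_q, l)), character(1)),
    mapq = rep(mapq, n), strand = rep(strand, length.out = n),
    sample = sample, chrom = "chr1",
    start = rep(start0, length.out = n),
    cigar = if (is.null(cigar)) paste0(nchar(seqs), "M") else cigar,
    is_duplicate = FALSE, is_secondary = FALSE, is_supplementary = FALSE,
    is_proper_pair = TRUE, stringsAsFactors = FALSE)
}

# independent global Needleman-Wunsch oracle (Biostrings)
nw_score <- function(a, b, match = 2, mismatch = -4, open = 4, ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  as.numeric(Biostrings::score(Biostrings::pairwiseAlignment(
    b, a, type = "global", substitutionMatrix = mat, gapOpening = open,
    gapExtension = ext)))
}

# spell the haplotype produced by applying one variant to a window
apply_variant_oracle <- function(window, pos, ref, alt, window_start = 0L) {
  rel <- pos - 1L - window_start
  stopifnot(substring(window, rel + 1L, rel + nchar(ref)) == ref)
  paste0(substring(window, 1L, rel), alt,
         substring(window, rel + nchar(ref) + 1L, nchar(window)))
}

# brute-force count of k-mers shared by >= min_support reads and absent from
# the reference (active-region oracle)
novel_kmer_oracle <- function(read_seqs, ref, k, min_support) {
  ref_k <- unique(somagraph:::kmerize(ref, k))
  per_read <- lapply(read_seqs, function(s)
    unique(somagraph:::kmerize(s, k)))
  tab <- table(unlist(per_read))
  tab <- tab[!names(tab) %in% ref_k]
  sum(tab >= min_support) > 0
}

# deterministic small tumor/normal fixture around one somatic spec
fixture_somatic <- function(specs, seed = 7L, length = 1200L,
                            error_rate = 0, tumor_cov = 80, normal_cov = 60,
                            dir = withr::local_tempdir(.local_envir =
                                                         parent.frame())) {
  simulate_tumor_normal(specs, out_dir = dir, length = length,
                        tumor_cov = tumor_cov, normal_cov = normal_cov,
                        error_rate = error_rate, seed = seed)
}
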