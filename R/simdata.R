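# Seeded tumor/normal read simulator.
#
# The generator emulates matched short-read WGS at desk scale: a random
# reference contig, diploid normal haplotypes with optional germline variants,
# a tumor sample modelled as a mixture of tumor cells (carrying the somatic
# variants on one haplotype) and contaminating normal cells, and paired
# 148-bp reads with known alignments. Reads are written with their true
# positions and CIGARs derived from the haplotype-to-reference edit map, so no
# external aligner is involved and every read's origin is known exactly.
#
# Somatic VAF model: a heterozygous somatic variant at tumor VAF v is realised
# with tumor purity p = 2v, i.e. haplotype weights
#   [hapA + somatic] v, [hapA] 0.5 - v, [hapB] 0.5,
# which leaves germline VAFs at 0.5/1.0 and puts the somatic alt read
# fraction at exactly v in expectation. All somatic specs in one run share a
# single tumor_vaf (one clone).

with_seed_local <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a seeded random reference sequence
#'
#' @param length Contig length in bp.
#' @param seed Integer seed; the sequence is fully deterministic per seed.
#' @return Single character string of uniform-random A/C/G/T.
#' @export
sim_reference <- function(length, seed) {
  stopifnot(length > 0)
  with_seed_local(seed,
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = ""))
}

#' Construct a variant specification table
#'
#' Alleles use the anchored VCF convention: for indels the first base of ref
#' and alt is the shared anchor base. `pos0` is the 0-based position of the
#' first ref base.
#'
#' @param pos0,ref,alt,zygosity,origin,tumor_vaf Per-variant columns;
#'   `zygosity` in `c("het","hom")`, `origin` in `c("somatic","germline")`,
#'   `tumor_vaf` only used for somatic specs.
#' @return data.frame of class `variant_specs`.
#' @export
variant_specs <- function(pos0 = integer(0), ref = character(0),
                          alt = character(0),
                          zygosity = rep("het", length(pos0)),
                          origin = rep("somatic", length(pos0)),
                          tumor_vaf = rep(0.5, length(pos0))) {
  stopifnot(all(zygosity %in% c("het", "hom")),
            all(origin %in% c("somatic", "germline")))
  df <- data.frame(pos0 = as.integer(pos0), ref = toupper(ref),
                   alt = toupper(alt), zygosity = zygosity, origin = origin,
                   tumor_vaf = as.numeric(tumor_vaf), stringsAsFactors = FALSE)
  df <- df[order(df$pos0), , drop = FALSE]
  if (nrow(df) > 1) {
    ends <- df$pos0 + nchar(df$ref)
    if (any(df$pos0[-1] < ends[-nrow(df)])) stop("overlapping variant specs")
  }
  class(df) <- c("variant_specs", "data.frame")
  df
}

# Apply a set of anchored edits to a reference string; returns the haplotype
# sequence plus the block map used to derive read CIGARs. Blocks are
# data.frame(type in M/I/D, ref_start, ref_len, hap_start, hap_len),
# 0-based, in order.
apply_edits <- function(reference, edits) {
  ref_len <- nchar(reference)
  if (nrow(edits) > 0) {
    ok <- substring(reference, edits$pos0 + 1L,
                    edits$pos0 + nchar(edits$ref)) == edits$ref
    if (!all(ok)) {
      stop("spec ref allele does not match reference at pos0=",
           edits$pos0[!ok][1])
    }
  }
  blocks <- list()
  pieces <- character(0)
  cur_ref <- 0L
  cur_hap <- 0L
  add_block <- function(type, rs, rl, hs, hl) {
    blocks[[length(blocks) + 1L]] <<- data.frame(
      type = type, ref_start = rs, ref_len = rl, hap_start = hs, hap_len = hl,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos0[i]
    r <- edits$ref[i]
    a <- edits$alt[i]
    lr <- nchar(r)
    la <- nchar(a)
    if (p > cur_ref) {
      len <- p - cur_ref
      add_block("M", cur_ref, len, cur_hap, len)
      pieces <- c(pieces, substring(reference, cur_ref + 1L, p))
      cur_ref <- p
      cur_hap <- cur_hap + len
    }
    m <- min(lr, la)
    add_block("M", cur_ref, m, cur_hap, m)
    pieces <- c(pieces, substring(a, 1L, m))
    cur_ref <- cur_ref + m
    cur_hap <- cur_hap + m
    if (lr > la) {
      add_block("D", cur_ref, lr - la, cur_hap, 0L)
      cur_ref <- cur_ref + (lr - la)
    } else if (la > lr) {
      add_block("I", cur_ref, 0L, cur_hap, la - lr)
      pieces <- c(pieces, substring(a, m + 1L, la))
      cur_hap <- cur_hap + (la - lr)
    }
  }
  if (cur_ref < ref_len) {
    len <- ref_len - cur_ref
    add_block("M", cur_ref, len, cur_hap, len)
    pieces <- c(pieces, substring(reference, cur_ref + 1L, ref_len))
  }
  blocks <- do.call(rbind, blocks)
  list(seq = paste(pieces, collapse = ""), blocks = blocks)
}

#' Build normal and tumor haplotypes from variant specs
#'
#' @param reference Reference sequence (character string).
#' @param specs A [variant_specs()] table.
#' @return List with `normal` and `tumor`, each a list of haplotypes
#'   `list(seq, blocks, weight)`; normal weights are 0.5/0.5.
#' @export
build_haplotypes <- function(reference, specs) {
  germ <- specs[specs$origin == "germline", , drop = FALSE]
  som <- specs[specs$origin == "somatic", , drop = FALSE]
  germ_a <- germ  # het germline variants go on haplotype A
  germ_b <- germ[germ$zygosity == "hom", , drop = FALSE]
  hap_a <- apply_edits(reference, germ_a)
  hap_b <- apply_edits(reference, germ_b)
  normal <- list(c(hap_a, weight = 0.5), c(hap_b, weight = 0.5))
  if (nrow(som) == 0) {
    tumor <- normal
  } else {
    v <- unique(som$tumor_vaf)
    if (length(v) != 1) stop("all somatic specs must share one tumor_vaf")
    if (v <= 0 || v > 0.5) stop("tumor_vaf must be in (0, 0.5]")
    if (any(som$zygosity != "het")) stop("somatic specs must be het")
    carrier_edits <- rbind(germ_a, som)
    carrier_edits <- carrier_edits[order(carrier_edits$pos0), , drop = FALSE]
    carrier <- apply_edits(reference, carrier_edits)
    tumor <- list(c(carrier, weight = v),
                  c(hap_a, weight = 0.5 - v),
                  c(hap_b, weight = 0.5))
    tumor <- Filter(function(h) h$weight > 0, tumor)
  }
  list(normal = normal, tumor = tumor)
}

# Map a haplotype interval [s, e) (0-based) through the block map to a
# reference position and CIGAR. Returns list(ref_pos, cigar) with
# leading/trailing insertions soft-clipped; a read with no reference-consuming
# bases is anchored at the insertion point as 1M + soft-clip.
hap_interval_to_ref <- function(blocks, s, e) {
  ops <- character(0)
  lens <- integer(0)
  ref_pos <- NA_integer_
  push <- function(op, len) {
    if (len <= 0) return()
    n <- length(ops)
    if (n > 0 && ops[n] == op) lens[n] <<- lens[n] + len
    else { ops <<- c(ops, op); lens <<- c(lens, len) }
  }
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (b$type == "D") {
      # deletion sits between haplotype positions; emit only when interior
      if (b$hap_start > s && b$hap_start < e) push("D", b$ref_len)
      next
    }
    bs <- max(s, b$hap_start)
    be <- min(e, b$hap_start + b$hap_len)
    if (bs >= be) next
    if (b$type == "M") {
      if (is.na(ref_pos)) ref_pos <- b$ref_start + (bs - b$hap_start)
      push("M", be - bs)
    } else {
      push("I", be - bs)
    }
  }
  # soft-clip insertion overhangs at the read ends
  if (length(ops) > 0 && ops[1] == "I") ops[1] <- "S"
  n <- length(ops)
  if (n > 0 && ops[n] == "I") ops[n] <- "S"
  # drop dangling deletions at either end (no aligned base beyond them)
  while (length(ops) > 0 && ops[1] == "D") { ops <- ops[-1]; lens <- lens[-1] }
  n <- length(ops)
  while (n > 0 && ops[n] == "D") { ops <- ops[-n]; lens <- lens[-n]; n <- n - 1 }
  if (!any(ops == "M")) {
    # fully inside an insertion: anchor one base at the attachment point
    att <- blocks$ref_start[blocks$type == "I" & blocks$hap_start <= s &
                              s < blocks$hap_start + blocks$hap_len][1]
    total <- e - s
    return(list(ref_pos = att, cigar = if (total > 1)
      paste0("1M", total - 1L, "S") else "1M"))
  }
  list(ref_pos = ref_pos, cigar = make_cigar(lens, ops))
}

#' Simulate paired reads for one sample and write a sorted, indexed BAM
#'
#' @param haplotypes List of `list(seq, blocks, weight)` as produced by
#'   [build_haplotypes()] (one sample's entry).
#' @param chrom Contig name used in the BAM.
#' @param ref_len Reference contig length (for the header).
#' @param coverage Target mean depth.
#' @param read_len Read length (default 148).
#' @param fragment_mean,fragment_sd Fragment size distribution (default
#'   350 +/- 50).
#' @param error_rate Per-base substitution error rate; base qualities encode
#'   this rate (Q60 when 0).
#' @param seed Integer seed; output is byte-deterministic per seed.
#' @param bam_path Output BAM path (".bam").
#' @param read_prefix Read-name prefix (e.g. "t" / "n").
#' @return `bam_path`, invisibly.
#' @export
sim_reads <- function(haplotypes, chrom, ref_len, coverage, read_len = 148L,
                      fragment_mean = 350, fragment_sd = 50,
                      error_rate = 0.001, seed = 1L, bam_path,
                      read_prefix = "r") {
  stopifnot(read_len < fragment_mean, coverage > 0)
  weights <- vapply(haplotypes, `[[`, numeric(1), "weight")
  weights <- weights / sum(weights)
  hap_lens <- vapply(haplotypes, function(h) nchar(h$seq), integer(1))
  # fragments cannot start within one fragment length of the contig end, so
  # normalize the count to hit the target depth over interior positions
  eff_len <- max(ref_len - fragment_mean, ref_len / 2)
  n_frag <- as.integer(ceiling(coverage * eff_len / (2 * read_len)))
  recs <- with_seed_local(seed, {
    hap_idx <- sample.int(length(haplotypes), n_frag, replace = TRUE,
                          prob = weights)
    flen <- as.integer(round(stats::rnorm(n_frag, fragment_mean, fragment_sd)))
    flen <- pmax(flen, read_len + 2L)
    flen <- pmin(flen, hap_lens[hap_idx])
    fstart <- as.integer(floor(stats::runif(n_frag) *
                                 (hap_lens[hap_idx] - flen + 1L)))
    q <- error_rate_to_q(error_rate)
    qual <- phred_to_string(rep(q, read_len))
    out <- vector("list", 2L * n_frag)
    for (i in seq_len(n_frag)) {
      h <- haplotypes[[hap_idx[i]]]
      s1 <- fstart[i]
      s2 <- fstart[i] + flen[i] - read_len
      seq1 <- substring(h$seq, s1 + 1L, s1 + read_len)
      seq2 <- substring(h$seq, s2 + 1L, s2 + read_len)
      if (error_rate > 0) {
        seq1 <- add_substitution_errors(seq1, error_rate)
        seq2 <- add_substitution_errors(seq2, error_rate)
      }
      m1 <- hap_interval_to_ref(h$blocks, s1, s1 + read_len)
      m2 <- hap_interval_to_ref(h$blocks, s2, s2 + read_len)
      name <- sprintf("%s%06d:h%d", read_prefix, i, hap_idx[i])
      out[[2L * i - 1L]] <- list(name = name, flag = 99L, pos0 = m1$ref_pos,
                                 cigar = m1$cigar, seq = seq1, qual = qual,
                                 mate_pos0 = m2$ref_pos)
      out[[2L * i]] <- list(name = name, flag = 147L, pos0 = m2$ref_pos,
                            cigar = m2$cigar, seq = seq2, qual = qual,
                            mate_pos0 = m1$ref_pos)
    }
    out
  })
  pos <- vapply(recs, `[[`, integer(1), "pos0")
  o <- order(pos, vapply(recs, `[[`, character(1), "name"),
             vapply(recs, `[[`, integer(1), "flag"))
  recs <- recs[o]
  sam_lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, as.integer(ref_len)),
    vapply(recs, function(r) {
      tlen <- r$mate_pos0 - r$pos0
      tlen <- if (bitwAnd(r$flag, 16L) > 0L) -abs(tlen) - read_len else
        abs(tlen) + read_len
      paste(r$name, r$flag, chrom, r$pos0 + 1L, 60L, r$cigar, "=",
            r$mate_pos0 + 1L, tlen, r$seq, r$qual, sep = "\t")
    }, character(1)))
  sam_path <- paste0(tools::file_path_sans_ext(bam_path), ".sam")
  writeLines(sam_lines, sam_path)
  Rsamtools::asBam(sam_path,
                   destination = tools::file_path_sans_ext(bam_path),
                   overwrite = TRUE, indexDestination = TRUE)
  unlink(sam_path)
  invisible(bam_path)
}

add_substitution_errors <- function(seq, error_rate) {
  n <- nchar(seq)
  hit <- which(stats::runif(n) < error_rate)
  if (length(hit) == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in hit) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Simulate a complete tumor/normal fixture
#'
#' Writes an indexed reference FASTA, tumor and normal BAMs, and a truth VCF
#' into `out_dir`. The default parameters are the package's standard study
#' conditions: a 2,000-bp contig, 148-bp paired reads (fragments 350 +/- 50),
#' 80x tumor / 60x normal coverage, 0.1% substitution error.
#'
#' @param specs A [variant_specs()] table (may be empty).
#' @param out_dir Output directory (created if missing).
#' @param length Reference length.
#' @param tumor_cov,normal_cov Per-sample target coverage.
#' @param read_len,fragment_mean,fragment_sd,error_rate Read simulation
#'   parameters, see [sim_reads()].
#' @param seed Integer master seed; reference and both samples derive
#'   sub-seeds from it deterministically.
#' @param chrom Contig name.
#' @return List with paths `reference`, `tumor_bam`, `normal_bam`,
#'   `truth_vcf`, the truth `vcf_records` frame, and the haplotype structure.
#' @export
simulate_tumor_normal <- function(specs = variant_specs(), out_dir,
                                  length = 2000L, tumor_cov = 80,
                                  normal_cov = 60, read_len = 148L,
                                  fragment_mean = 350, fragment_sd = 50,
                                  error_rate = 0.001, seed = 7L,
                                  chrom = "chr1") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- sim_reference(length, seed)
  fa_path <- file.path(out_dir, "ref.fa")
  write_reference_fasta(stats::setNames(ref, chrom), fa_path)
  haps <- build_haplotypes(ref, specs)
  tumor_bam <- file.path(out_dir, "tumor.bam")
  normal_bam <- file.path(out_dir, "normal.bam")
  sim_reads(haps$tumor, chrom, length, tumor_cov, read_len, fragment_mean,
            fragment_sd, error_rate, seed = seed * 2L + 1L,
            bam_path = tumor_bam, read_prefix = "t")
  sim_reads(haps$normal, chrom, length, normal_cov, read_len, fragment_mean,
            fragment_sd, error_rate, seed = seed * 2L + 2L,
            bam_path = normal_bam, read_prefix = "n")
  truth <- truth_records(specs, chrom, reference = ref)
  truth_path <- file.path(out_dir, "truth.vcf")
  write_vcf(truth, reference_name = basename(fa_path), path = truth_path,
            contig_lengths = stats::setNames(length, chrom))
  list(reference = fa_path, tumor_bam = tumor_bam, normal_bam = normal_bam,
       truth_vcf = truth_path, truth = truth, haplotypes = haps,
       ref_seq = ref, chrom = chrom)
}

#' Truth VCF records for a spec table
#'
#' When `reference` is given, records are left-normalized against it so the
#' truth set uses the same canonical representation as the caller output.
#' @keywords internal
truth_records <- function(specs, chrom, reference = NULL) {
  if (nrow(specs) == 0) return(vcf_records())
  som <- specs$origin == "somatic"
  gt <- ifelse(specs$zygosity == "hom", "1/1", "0/1")
  pos <- specs$pos0 + 1L
  ref <- specs$ref
  alt <- specs$alt
  if (!is.null(reference)) {
    for (i in seq_len(nrow(specs))) {
      nv <- left_normalize(pos[i], ref[i], alt[i], reference, 0L)
      pos[i] <- nv$pos
      ref[i] <- nv$ref
      alt[i] <- nv$alt
    }
  }
  o <- order(pos, ref, alt)
  vcf_records(chrom = rep(chrom, nrow(specs)), pos = pos[o], ref = ref[o],
              alt = alt[o],
              filter = rep("PASS", nrow(specs)),
              gt_normal = ifelse(som, "0/0", gt)[o],
              gt_tumor = gt[o],
              origin = specs$origin[o],
              tvaf = ifelse(som, specs$tumor_vaf, NA_real_)[o])
}
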