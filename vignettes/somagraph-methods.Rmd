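---
title: "Somatic small-variant calling with joint local assembly graphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic small-variant calling with joint local assembly graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somagraph)
```

# The problem

Alignment-based somatic callers lose sensitivity for insertions and
deletions in the 30–250 bp range because individual reads spanning such
events are mapped with clipped or shattered alignments against the linear
reference (reference bias). `somagraph` follows the local micro-assembly
strategy: tumor and normal reads over a small genomic window are assembled
*jointly* into a colored de Bruijn graph, candidate haplotypes are extracted
as graph paths, variants are read off a multiple alignment of those
haplotypes against the local reference, and every read is then re-aligned to
the haplotypes to quantify allele support in each sample.

This vignette documents the model, the tunable parameters and their
defaults, the numerical choices, and the known limitations. It states no
empirical result that the package's test suite does not itself compute.

# Windowing

The genome is processed in consecutive, overlapping windows
(`window_size = 600` bp, `overlap = 250` bp, so the step is 350 bp). The
overlap exceeds the read length (148 bp in the bundled simulator), so every
variant smaller than the overlap lies fully interior to at least one window;
merging deduplicates variants discovered in two windows, keeping the copy
with the higher somatic score (ties resolve to the lower window index).
Windows are independent work units: processing order — and hence any worker
count — cannot change the merged output. The test suite asserts
byte-identical VCFs across worker counts.

A window is *active* (worth assembling) iff at least `min_active_support = 2`
reads share a k-mer absent from the local reference, or any read's CIGAR
shows an insertion, a deletion, or a soft clip of `min_clip = 5`+ bases. The
novel-k-mer test uses the reference context expanded by ~200 bp so that read
overhangs past the window edges do not masquerade as novel sequence.
Requiring two reads suppresses isolated sequencing errors (a singleton
novel k-mer) while catching real events at any plausible allele fraction.

# Joint assembly

**k selection.** The smallest odd k in 11–101 (step 2) such that no k-mer
repeats on the forward strand of the window reference. Odd k avoids
palindromic self-overlap; uniqueness makes the reference spell a simple
source-to-sink path. If the *variant* haplotype itself contains a k-mer
repeat (possible for long insertions), path extraction detects the resulting
graph cycle and the window is re-assembled at k + 10 until the extracted
paths are simple or k exceeds the maximum.

**Graph.** Nodes are k-mers from the window reference and from both samples'
reads, with per-color (tumor/normal) occurrence counts; edges are (k+1)-mers
with traversal counts. Read bases below `min_base_q = 10` break the read
into fragments before k-merization. Reads are used in the orientation the
BAM stores (reference orientation), so no canonical-k-mer folding is needed.

**Cleaning.** To a fixpoint: non-reference nodes with combined coverage
below `min_node_cov = 2` are removed, then dead-end branches ("tips") of at
most k nodes that do not end at the source/sink. Reference-path nodes are
never removed, so the cleaned graph always spells the window reference; the
suite checks cleaning is monotone and idempotent.

**Path extraction.** Haplotype contigs are pulled out by iterative BFS
shortest-path extraction in the spirit of Edmonds–Karp augmentation: each
round takes the shortest source-to-sink path that still traverses at least
one unused edge (ties: higher minimum edge support, then lexicographically
smaller k-mer), then marks its edges used. Requiring fresh capacity in every
augmenting path is what guarantees both termination and that each true
haplotype branch appears in some extracted path. An earlier design that
decremented a shared bottleneck capacity was rejected: a Poisson coverage
dip on the trunk (shared by all haplotypes) would be saturated by the first
extraction and disconnect the sink before the second haplotype was seen.
Non-simple paths (node revisits, only possible when a k-mer repeat makes
the graph cyclic) are discarded — their capacity is consumed and k is
escalated as described above. Windows still offering unexplored paths after
`max_paths = 16` extractions are demoted to "no calls" with a reason code;
this is a precision guard for repeat-dense windows, and it means a
two-branch bubble queried with `max_paths = 1` is demoted rather than
truncated.

# Variant discovery by partial-order alignment

The local reference and the contigs (added in order of descending minimum
edge support) are aligned progressively into a partial-order graph: each new
sequence is aligned to the graph by global sequence-to-DAG dynamic
programming and fused into it; aligned nodes share an "alignment ring", and
rings become MSA columns. For a single contig against the initial reference
chain this DP *is* global Needleman–Wunsch, which the tests verify against
an independent implementation on random pairs.

Scoring is match +2, mismatch −4, gap open −4, gap extend −2 (a gap of
length L costs 4 + 2L), global ends. This scoring is shared with read
realignment so contig and read alignments are mutually consistent; it is
deliberately indel-tolerant, as is usual when aligning reads against
assembled haplotypes.

Per non-reference row, maximal runs of difference columns become one event
each: pure reference-gap runs become insertions, pure row-gap runs become
deletions (both anchored on the previous reference base, the VCF
convention), and mixed runs become block substitutions. Events from
different rows that coincide after anchoring are emitted once with all
source rows recorded. Every event is then left-normalized: shared suffixes
are trimmed (re-anchoring leftwards when an allele would empty), then shared
prefixes, leaving one anchor base for indels. The suite checks
left-normalization never changes the spelled haplotype and is idempotent,
on hundreds of randomized repeat contexts.

# Realignment genotyping

Every read in the window is re-aligned glocally (read fully aligned, free
target end gaps) to the local reference and to each contig. The compiled
kernel takes three routes, all provably score-identical to the full dynamic
program under this scoring: exact substring; seeded ungapped placement with
at most one mismatch (a mismatch costs 6, any gap at least 6 while also
losing a match); and exact-overlap clipped placement for reads overhanging
a target end. Everything else takes the full affine DP with the
deterministic tie order diagonal > up > left.

Alignments are ranked by gap-compressed identity (matches / (matches +
mismatches + gap *openings*)) and then score; the best target wins. For each
candidate variant the read supports the allele whose exact sequence it
carries over the allele span plus `min_flank = 1` anchor base on each side
of the winning target; one increment per read per variant. Two guards
matter in practice:

* when a read ties between targets that *disagree* at a variant, it is
  uninformative for that variant (depth only) — ties between targets that
  agree are harmless and common when several contigs exist;
* reads whose best alignment has gap-compressed identity below
  `min_identity = 0.85` contribute nothing. Reads that overlap a window by
  only a handful of bases have no faithful full-length alignment, and their
  chaotic placements can otherwise fabricate junction-spanning support for
  long deletions.

Genotypes per sample maximize the binomial likelihood of the alt count among
allele fractions e, 0.5 and 1−e with e = 0.001 (a conventional short-read
substitution rate); no informative reads gives `./.`.

# Somatic scoring

Each candidate carries window-level (percent high-quality reads per sample;
high quality = mapping quality ≥ 20, not duplicate/secondary/supplementary),
variant-level (type, length, depth per sample, absolute tumor−normal VAF
difference) and allele-level (allele counts, strand bias = min(fwd,rev)/
(fwd+rev) over alt reads, mean alt base and mapping quality) features.

The classifier is a glass-box cyclic additive boosting model: each feature
owns a binned shape function (quantile bins, ≤ 64); training cycles the
features in fixed order, fitting one depth-1 split per feature per round on
the logistic-loss gradient with Newton leaf values scaled by the learning
rate (0.1, 500 rounds by default). An update that would increase the
training loss is halved deterministically (up to 20 times) before
application, making the loss non-increasing by construction rather than by
hope. Shapes are centered to mean zero over the training distribution with
the means folded into the intercept, so every prediction decomposes exactly:
logit(p) = intercept + Σ per-feature contributions. Training is fully
deterministic given data and seed (the seed only enters through
under-sampling, which keeps all positives and at most 30 negatives per
positive — the class imbalance treatment).

Calls PASS when the candidate has a somatic genotype configuration (tumor
carries the alt allele, normal is 0/0) and, when a model is supplied, the
somatic probability reaches the type threshold: 0.90 for SNV/MNV, 0.95 for
insertions and deletions (boundaries inclusive, user-overridable). The VCF
dialect deliberately has only two FILTER values, so germline candidates,
artifacts and sub-threshold calls are all `LowScore`; the full candidate
table with genotypes remains available to distinguish them. MNVs use the
SNV threshold because they are substitution-like.

# Two-tech truth-set rescue

Given a short-read and a long-read call set over the same sample, variants
matching on (chrom, pos, ref, alt) after left-normalization are `COMMON`.
Platform-unique variants are checked in the *other* platform's alignments by
direct pileup-style counting: coverage is the number of passing reads
spanning the locus, alt reads those carrying the exact alt allele with one
matching flank base on each side. A unique variant is rescued
(`LR_ORIGIN` / `ILMN_ORIGIN`) iff at least 2 alt reads are seen at coverage
≥ 20, else `DROPPED`; coverage here is filtered depth (reads passing
mapping-quality filters), a deliberate reading where raw depth would have
been the alternative. Exact normalized matching is a simplification of
haplotype-aware call-set comparison: two representations of the same
haplotype that differ in event *decomposition* (not just position) will not
match. BED exclusion removes variants whose 0-based position falls in any
half-open region.

# The read simulator

The simulator is the package's study-condition generator, not a fixture: a
uniform-random reference contig; diploid normal haplotypes with optional
germline variants; a tumor sample modelled as tumor cells (purity p = 2·VAF,
carrying all somatic variants on one haplotype) mixed with normal cells, so
a heterozygous somatic variant at `tumor_vaf` v yields alt-read fraction v
exactly while germline VAFs stay at 0.5/1.0. Reads are 148 bp pairs from
fragments of 350 ± 50 bp, with per-base substitution errors at 0.1% by
default and base qualities encoding that rate; defaults are 80× tumor and
60× normal, the character of a deep short-read WGS pair at desk scale.
Reads carry their *true* positions and CIGARs derived from the
haplotype-to-reference edit map (deletion-spanning reads carry D
operations; insertion overhangs become soft clips; the rare read entirely
inside a long insertion is anchored at the insertion point as 1M plus soft
clip, the closest valid SAM rendering). Fragment counts are normalized so
the target depth is achieved over interior positions, where fragments can
actually start on both sides.

What the simulator does **not** emulate: indel sequencing errors,
GC-coverage bias, mapping ambiguity from genome-wide repeats (each contig is
a single random sequence), long-read error profiles, and real
tumor heterogeneity beyond a single clone. Passing tests therefore
demonstrate algorithmic correctness under clean, known conditions — not
performance on real cell-line data.

# Problem sizes used in the test suite

The package's own evaluation uses 1.2–3.6 kb contigs: variant-recovery
sweeps run each variant class (SNV; 1–10 bp insertions and deletions; 30,
70, 150 and 250 bp deletions and insertions) at tumor VAF 0.5 and 0.25 over
20 seeds on a 1.2 kb contig at the default 80×/60× coverage with error-free
reads; false-positive sweeps run 50 seeded variant-free tumor/normal pairs
with 0.1% errors; the worked deletion example uses a 2 kb contig; the
worker-determinism check uses a 10-window 3.6 kb contig. These sizes keep a
full run of the suite in the tens of minutes on one core while every window
still sees full-depth data.

# Known limitations

* Somatic status without a trained model reduces to the genotype
  configuration; a model is needed for a calibrated probability.
* Multi-allelic sites emerge as separate biallelic records; no phasing.
* Windows whose reference has no repeat-free k (long homopolymers or
  microsatellites spanning the whole window) are demoted, as are windows
  with more than `max_paths` distinct haplotype paths.
* The rescue module's exact normalized matching is weaker than
  haplotype-aware comparison for complex indel representations.
* VAF estimates for long deletions are upward-biased at depth because a
  ref-supporting read must span the entire deleted span plus flanks,
  whereas an alt-supporting read only spans the junction; genotype calls are
  robust to this but downstream users of AD should know it exists.
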