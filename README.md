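# somagraph

Somatic small-variant calling for matched tumor/normal short-read data by
joint local assembly, in R.

Alignment-based somatic callers struggle with insertions and deletions in
the 30–250 bp "twilight zone": reads spanning such events map to the linear
reference with clipped or shattered alignments, and the evidence never
reaches the caller. `somagraph` instead re-assembles each small genomic
window from the tumor and normal reads *jointly*:

1. **Window engine** — the genome is tiled into overlapping 600 bp windows
   (250 bp overlap); a window is assembled only when reads show evidence of
   non-reference sequence (shared novel k-mers, indel or clipped CIGARs).
2. **Colored de Bruijn assembly** — tumor reads, normal reads and the local
   reference build one k-mer graph with per-sample counts; after
   error-pruning, haplotype contigs are extracted by iterative
   shortest-path traversal with edge-capacity bookkeeping.
3. **Partial-order alignment (POA)** — the contigs and the local reference
   are progressively aligned into a partial-order graph (match +2,
   mismatch −4, gap −4 −2/base, global ends); candidate variants are read
   off the MSA columns, anchored, and left-normalized to canonical VCF
   representation.
4. **Realignment genotyping** — every read is re-aligned glocally to the
   reference and each contig; alignments are ranked by gap-compressed
   identity `matches / (matches + mismatches + gap_openings)` then score,
   and each read contributes at most one allele count per variant, by exact
   sequence match over the allele ± 1 flank base. Genotypes maximize a
   binomial likelihood over allele fractions {e, ½, 1−e}, e = 0.001.
5. **Glass-box somatic scoring** — a cyclic additive boosting classifier
   over window/variant/allele-level features whose predictions decompose
   exactly as `logit(p) = intercept + Σ_f shape_f(x_f)`; default PASS
   thresholds are p ≥ 0.90 for SNVs and p ≥ 0.95 for indels. Training uses
   random under-sampling to ~30 negatives per positive.
6. **Two-tech truth rescue** — cross-platform truth-set construction:
   variants unique to one platform are rescued when the other platform's
   alignments show ≥ 2 alt reads at ≥ 20× coverage
   (COMMON / LR_ORIGIN / ILMN_ORIGIN / DROPPED).
7. **GFA export** — each window's POA variant graph can be written as GFA v1
   (unbranched node runs as segments, `ref`/`hapN` paths spelling the input
   sequences exactly) for graph viewers.

A seeded read simulator (`simulate_tumor_normal()`) generates the full test
substrate — reference FASTA, tumor/normal BAMs with known true alignments,
and a left-normalized truth VCF — so everything is reproducible offline.

## Worked example

A 2 kb tumor/normal pair with one heterozygous 70 bp somatic deletion at the
contig midpoint (tumor VAF 0.5, 80× tumor / 60× normal, error-free reads):

```r
library(somagraph)

ref <- sim_reference(2000, seed = 7)
del <- substring(ref, 1001, 1071)                  # 70 bp + anchor base
specs <- variant_specs(pos0 = 1000, ref = del, alt = substring(del, 1, 1),
                       zygosity = "het", origin = "somatic", tumor_vaf = 0.5)
fx <- simulate_tumor_normal(specs, out_dir = "demo", length = 2000,
                            seed = 7, error_rate = 0)
res <- call_somatic(fx$tumor_bam, fx$normal_bam, fx$reference)
res$records[, c("chrom", "pos", "vtype", "vlen", "filter",
                "gt_normal", "gt_tumor", "ad_ref_tumor", "ad_alt_tumor")]
#>   chrom  pos vtype vlen filter gt_normal gt_tumor ad_ref_tumor ad_alt_tumor
#> 1  chr1 1000   DEL   70   PASS       0/0      0/1           22           57
```

One record: a 70 bp deletion at position 1000 (the left-normalized anchor),
PASS, absent from the normal (`0/0`), heterozygous in the tumor (`0/1`) with
57 of 79 informative tumor reads carrying the deletion junction. The
apparent excess of alt reads is a spanning artifact of long deletions —
a ref-supporting read must span all 70 deleted bases, an alt-supporting read
only the junction — discussed in the methods vignette.

`vignettes/somagraph-methods.Rmd` documents the model, every tunable
parameter, and the design decisions; `exec/somagraph` is a thin CLI over the
same functions (`simulate`, `call`, `train`, `score`, `rescue`).

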