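# regulogR

Comparative-genomics reconstruction of bacterial transcription-factor
regulons, built around the regulatory logic of the MocR subfamily
(GntR-family regulators with a PLP-binding aminotransferase-like sensory
domain). These TFs bind operators made of short repeated **boxes** —
direct or inverted repeats of two to four subunits spaced near multiples
of the DNA helical turn — and most of them have never been characterized
experimentally, so their regulons are inferred by comparing upstream
regions of orthologous genes across related genomes.

The package is for computational biologists reconstructing prokaryotic
regulons (or benchmarking regulon-inference methods) and implements the
full chain:

* **Genome model** — FASTA + gene-table (TSV/GFF3) input, strand-aware
  upstream windows (−350..+50 nt around the translation start), operon
  prediction from intergenic distances (≤ 200 nt, same strand) with an
  optional cross-genome persistence filter.
* **Motif discovery** — phylogenetic footprinting by spaced-dyad seeding
  (word/word, word/reverse-complement pairs at 5–40 nt gaps, ranked by
  background-corrected z-score) and deterministic greedy PWM refinement,
  with detection of additional conserved boxes in the flanks and the
  inter-box gap.
* **PWM scanning** — log-count PWM with 0.5 pseudocount,
  `w(b,k) = ln(N(b,k)+0.5) − ¼ Σ_b′ ln(N(b′,k)+0.5)`, additive site
  scores, threshold 10% below the lowest training-site score
  (`T = m − 0.1·|m|`), both-strand scanning, and a positional rescue
  rule for weak sites (another 10% below `T`) anchored on the median
  strong-site position of orthologs.
* **Regulon assembly** — candidate operons from lead-gene hits, a
  consistency check admitting an orthologous family only when supported
  in ≥ `K(N) = max(2, ⌈N/3⌉)` of `N` genomes, and expansion of accepted
  members to whole operons; cross-genome bundles are **regulogs**.
* **Motif structure** — box orientations (arrows `>`/`<`), edge-to-edge
  distances, strand canonicalization, and classification into the ten
  observed arrangement categories from `> >` to `> > < >`.
* **Synthetic data** — a deterministic generator planting divergons
  (TF divergently transcribed from its first target operon), member and
  decoy operons, ortholog families, and operator sites sampled from a
  configurable box profile, with a complete ground-truth manifest.
* **Reports** — arrangement distributions, per-taxon TF statistics, and
  the bundled summary tables of a published 390-genome MocR-subfamily
  reconstruction for the arithmetic helpers.

## Worked example

Generate a synthetic taxon group, discover the operator motif from the
upstream regions of the regulon members, and reconstruct the regulog:

```r
library(regulogR)

cfg <- generator_config(seed = 42)   # 10 genomes, 5 member + 3 decoy families
ds  <- plant_regulog(cfg)
ds
#> <synthetic_dataset> 10 genomes, 50 planted sites (> >, gap 13)

gt <- ds$ground_truth
regions <- lapply(seq_len(nrow(gt$sites)), function(i)
  extract_upstream(ds$genomes[[gt$sites$genome_id[i]]], gt$sites$gene_id[i]))

model <- discover_motif(regions)
model
#> <motif_model> 2 boxes (> >), box width 8, gap(s) 13
#>   shared box consensus: TGTAAAAC
#>   sites in 50/50 regions; objective (mean IC x coverage) 1.489

classify_structure(model)
#> <arrangement> > > (category: > >), gaps: 13 nt

res <- reconstruct_regulog(ds$genomes, regions, group_id = "tf_family")
res$regulog
#> <regulog> tf_family (SyntheticTaxon): 10 regulons in 10 genomes, 58 sites, 110 target genes (K = 4)

membership_scores(res$regulog, gt$membership)[c("precision", "recall", "f1")]
#> $precision [1] 1
#> $recall    [1] 1
#> $f1        [1] 1
```

The discovered model matches the planted operator exactly: two direct
boxes (`> >`) of width 8 with consensus `TGTAAAAC` — the conserved 5′
`TGT` group typical of this TF family — separated by 13 nt (start to
start 21 nt, two DNA helical turns), with a site found in all 50
training regions at about 1.5 bits per column. The reconstructed regulog
contains all 10 per-genome regulons; `K = 4` is the consistency-check
threshold for a 10-genome group. The 110 target genes are the member
operons expanded to all of their genes; none of the 3 decoy families is
pulled in (precision 1).

Real data enter through `read_genome()` (FASTA + TSV or GFF3, plus
optional protein FASTA) and, ideally, a curated ortholog table via
`read_ortholog_groups()` in place of the built-in reciprocal-best-hit
surrogate.

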