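# cardiosex

Sex-stratified analysis of cardiac-development transcriptomes, as an R
package. Male (XY) and female (XX) mouse embryos diverge transcriptionally
long before gonads form: embryonic stem (ES) cells already show hundreds of
sex-biased genes, and a subset of transcription factors (TFs) and
epigenetic/remodelling enzymes (EREs) keeps, loses, acquires or even
reverses its bias as ES cells differentiate into cardiac precursors (CP),
embryonic hearts (8.5–10.5 days post coitum), neonatal (P1) and adult
hearts. `cardiosex` implements the full analytical toolchain needed to
detect and track such biases, plus synthetic-data generators with ground
truth so every stage is testable offline.

## What it computes

- **Single-cell sex inference** — per cell, the ratio of *Xist* (X-linked,
  female-high) to *Eif2s3y* (Y-linked, male-only) FPKM: ratio ≥ 1.5 →
  female, ratio < 1 → male; the undefined gap [1, 1.5) is flagged
  ambiguous and excluded from testing.
- **Per-stage differential bias** — genes with FPKM < 1 are treated as not
  expressed; Welch's *t* on log2(FPKM+1) per gene, Benjamini–Hochberg FDR,
  bias `XX`/`XY`/`nb` at q < α (α = 0.05 for single-cell stages, 0.01 for
  the cardiac-precursor bulk comparison).
- **Weighted co-expression networks** — unsigned similarity
  S<sub>mn</sub> = |cor(m,n)|, soft-threshold adjacency
  a<sub>mn</sub> = S<sub>mn</sub><sup>β</sup> with β chosen as the lowest
  power giving approximate scale-free topology, topological overlap
  TOM, average-linkage clustering, modules of ≥ 50 genes, module
  eigengenes (first principal components) and their correlation with sex.
- **Bias trajectories** — per-gene stage codes (`XX`/`XY`/`nb`/absent)
  classified into groups I–V around the gonadogenesis boundary
  (E10.5 | P1), with maintain/lose/acquire/reverse transition counts.
- **Protein-interaction topology** — STRING-style edge lists filtered at
  combined score ≥ 0.7 with text-mining-only edges dropped; Louvain
  community detection, degree/betweenness/closeness centralities and a
  mean-rank hub score.
- **Promoter motif scanning** — JASPAR PFMs → log-odds PWMs, exact null
  score distributions by dynamic programming, score thresholds at p ≤ 1e-5,
  both-strand scanning of −5000..+1000 promoter windows, hypergeometric
  (ZOOPS) set enrichment.
- **Chromatin metaprofiles** — binned coverage matrices around TSS/enhancer
  anchors, bootstrap average profiles, Mann–Whitney group comparison.

## Worked example

A synthetic 6+6 ES-line panel with a planted 60-gene module whose latent
factor correlates r = 0.85 with sex, mirroring the design that yielded the
sex-associated module in real ES data:

```r
library(cardiosex)
sim <- simulate_bulk_panel(n_per_sex = 6, n_genes = 400, n_biased = 0,
                           module_size = 60, r_module = 0.85, seed = 2)
res <- wgcna_modules(sim$matrix, min_size = 50)
res$trait_correlation
#>      module          r            p
#> 1 turquoise 0.84743849 0.0005008733
#> 2      blue 0.06807693 0.8334978572
```

The top module recovers all 60 planted genes, and its eigengene–sex
correlation (0.847, p ≈ 5e-4) sits at the planted value. Sexing a
synthetic single-cell panel at 30 % dropout:

```r
sc <- simulate_cells(n_cells = 500, dropout = 0.3, seed = 2)
calls <- sex_cells(sc$matrix)
table(calls$call)
#>     female       male unassigned
#>        199        189        112
```

Accuracy on the usable (non-ambiguous) calls is 0.977; unassigned cells are
those with both markers dropped out. Classifying the shipped transcription
of the developmental bias tables (`inst/extdata/tables_2_3_transcription.tsv`,
60 female- and 61 male-biased TFs/EREs):

```r
bt <- read_bias_table_tsv(system.file("extdata",
        "tables_2_3_transcription.tsv", package = "cardiosex"))
table(classify_trajectories(bt)$group)
#>    I   II  III   IV lost    V
#>   51   17    5   11    4   33
transition_summary(bt, "ES", "Adult")
#> maintain     lose  acquire  reverse
#>       12        9       12        4
```

Group I genes are biased in ES cells and silent thereafter; group V biases
appear only after gonadogenesis (P1/Adult), i.e. under possible hormonal
influence. The 12 maintain calls are the ES↔Adult conserved biases among
the tabulated regulators (3 female, 9 male); the 4 reversals are
Meis2/Zfp9 (female→male) and Dot1l/Zfp296 (male→female).

There is also a command-line front end (`exec/cardiosex`) with subcommands
`simulate`, `sex-cells`, `de`, `wgcna`, `trajectory`, `ppi`, `motif-scan`,
`promoters`, `profile` and `run` (the seeded, manifest-writing synthetic
end-to-end pipeline).

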