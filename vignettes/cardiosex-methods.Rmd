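---
title: "cardiosex: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cardiosex: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiosex)
```

# The problem

Sex-biased gene expression is usually studied in adult tissues, where
hormones dominate. But XX and XY embryos differ transcriptionally from the
embryonic stem (ES) cell stage onward — before gonads, before hormones —
and some of those early biases in transcription factors (TFs) and
epigenetic/remodelling enzymes (EREs) persist into, or re-emerge in, the
adult heart. `cardiosex` packages the analytical machinery for this
question: sexing single cells, calling per-stage expression biases,
finding sex-associated co-expression modules, classifying cross-stage bias
trajectories, and interrogating interaction networks, promoter motifs and
chromatin profiles. Everything runs on synthetic data with known ground
truth, so the statistical behaviour of each stage is testable without any
external download.

# Data model and filters

Expression is handled as FPKM in a genes × samples matrix with gene
(`gene_id`, `symbol`, `chromosome`, `tss`, `strand`, `reg_class`) and
sample (`sample_id`, `sex`, `stage`, `batch`, `cross`) annotations. The
stage set is ordered: ES < CP < E8.5 < E9.5 < E10.5 < P1 < Adult.

Two filters are applied before any statistics:

* **Presence.** A value below 1 FPKM is "not expressed". A gene counts as
  *expressed at a stage* when its mean FPKM over that stage's samples
  reaches 1 in at least one sex. The per-cell rule is stated upstream; the
  stage-level aggregation (mean within at least one sex) is this package's
  choice, made so that presence is a per-stage, per-gene property that the
  trajectory builder can consume, and so that a gene expressed in only one
  sex still counts as present (it may be the most interesting kind).
* **Zero variance.** Genes constant across all samples are removed; they
  carry no information for tests or correlations.

All downstream statistics run on log2(FPKM + 1). The sources are silent on
the scale their *t* tests used; log2(x+1) is the standard variance
stabilisation for FPKM and the choice is recorded here rather than
inferred. The boundary semantics are deliberate and tested: FPKM = 1.0 is
expressed ("< 1" is strict), ratio 1.5 calls female ("at least"), and
q = 0.05 is *not* significant ("< 0.05" is strict).

# Single-cell sexing

Each cell's sex comes from the ratio of *Xist* to *Eif2s3y* FPKM: at least
1.5 → female, below 1 → male. Two gaps in that rule needed decisions:

* **Ratio in [1, 1.5).** Neither printed threshold covers it. Such cells
  are labelled `ambiguous` and excluded from differential testing rather
  than forced to either side — the package does not invent a boundary the
  rule omits.
* **Zero denominators.** *Eif2s3y* = 0 with *Xist* > 0 yields ratio +Inf →
  female; this is the expected female signature (the Y marker is truly
  absent, not merely dropped out, in female cells). Both markers zero is
  uninformative: `unassigned`, excluded.

Ratios are computed on raw FPKM, not the log scale, matching the wording
of the rule. Calls are scale-invariant and monotone in *Xist* by
construction, and both properties are tested.

# Differential bias

Per stage, Welch's unequal-variance *t* (the sources say only "t test";
Welch is the robust choice for tiny, possibly unbalanced groups) on the
log scale, two-sided p, Benjamini–Hochberg step-up FDR (again, "FDR" is
all that is stated), and a bias call at q < α with the sign of the
female-minus-male difference: `XX` female-enriched, `XY` male-enriched,
`nb` otherwise. α defaults to 0.05 for single-cell stages and 0.01 for the
cardiac-precursor bulk comparison, the two thresholds the analyses used.
Genes failing presence in both sexes are reported `absent` and not tested;
genes present but constant across the stage's samples are reported `nb`
with NA statistics. Degenerate Welch inputs follow fixed conventions
(both groups constant and equal → t = 0, p = 1; constant and unequal →
±Inf, p = 0, flagged).

# Co-expression modules

The network is unsigned and follows the standard weighted co-expression
construction:

1. S<sub>mn</sub> = |cor(m, n)| (Pearson, log scale, all samples jointly);
2. a<sub>mn</sub> = S<sub>mn</sub><sup>β</sup>, diagonal zero;
3. topological overlap
   T<sub>mn</sub> = (Σ<sub>u≠m,n</sub> a<sub>mu</sub>a<sub>un</sub> + a<sub>mn</sub>) /
   (min(k<sub>m</sub>, k<sub>n</sub>) + 1 − a<sub>mn</sub>);
4. average-linkage clustering of 1 − T;
5. a top-down cut into modules of ≥ 50 genes;
6. eigengenes, module merging, and module–trait correlation.

Decisions worth recording:

* **β selection.** Candidate powers 1..20; for each, connectivities
  k<sub>m</sub> = Σ a<sub>mu</sub> are binned into 10 *logarithmically
  spaced* bins and log10(frequency) is regressed on log10(mean k); the fit
  index is R² signed by the slope (scale-free requires a negative slope),
  and the lowest power reaching 0.8 wins. Log-spaced binning is the
  field-standard way to fit power-law degree distributions and is the only
  binning under which an exactly power-law degree sequence scores R² = 1
  (a property the tests assert); equal-occupancy bins would make the
  frequency axis constant by construction. β is always data-derived — it
  is an output, never a configuration constant.
* **Tree cut.** A static cut at the 0.99 quantile of merge heights stands
  in for the full dynamic tree cut algorithm; only "top-down" and the
  minimum module size of 50 are specified upstream, and the hybrid
  algorithm is out of scope. The quantile is configurable and the
  substitution is flagged here deliberately.
* **Eigengenes.** First principal component of the per-gene standardised
  member submatrix, unit norm, sign fixed so the mean correlation with
  member profiles is nonnegative. Modules whose eigengenes correlate above
  1 − 0.25 are merged iteratively (closest pair first); 0.25 is a
  convention, not a value the sources state.
* **Trait encoding.** female = 1, male = 0, so positive r means
  female-associated. Gene significance is read as GS = −log10(p) (the
  stated "lgP" leaves base and sign open; this is the recorded
  interpretation), capped at 300 for p = 0; module significance is the
  mean GS over members.

# Bias trajectories

Per gene and stage the code is `XX`, `XY`, `nb`, or absent. Groups:

* **I** — biased in ES cells, not expressed at any later stage;
* **II / III** — biased in ES cells with later biases all in the same (II)
  or at least one opposite (III; III takes precedence) direction;
* **IV** — first bias after implantation but before gonadogenesis
  (CP..E10.5);
* **V** — first bias only at P1 or Adult;
* **lost** — ES-biased, expressed later but never biased again. The stated
  groups do not cover this case; it is kept separate rather than silently
  merged into I;
* **never_biased** otherwise.

The gonadogenesis boundary sits between E10.5 and P1: gonads differentiate
after E10.5, so biases up to E10.5 predate sex hormones. Group I is
strict: *any* later expression (even `nb`) disqualifies it. Transitions
(maintain / lose / acquire / reverse) are computed between consecutive
stages at which the gene is expressed, skipping absent stretches — a bias
that reappears in the opposite direction after a silent gap is still a
reversal (this is what makes the canonical male-to-female reversal genes
carry a `reverse` transition).

The package ships a transcription of the published tables of sex-biased
TFs/EREs (60 female- and 61 male-biased rows) as
`inst/extdata/tables_2_3_transcription.tsv`. The source text available for
transcription collapses table cells, so per-row stage placement was
reconstructed from the tables' group ordering and every explicit per-gene
statement in the accompanying text; the file header lists the judgment
calls, and the printed row totals serve as the transcription check. The
worked-example acceptance targets (row totals; the seven male-biased genes
that equalise in adult hearts; the two bias reversals per table; the two
X-linked female biases lost by adulthood; the one X-inactivation escapee
biased at all seven stages) are all insensitive to the remaining
within-group placement freedom.

# Interaction networks

STRING-style edge lists are filtered at combined score ≥ 0.7 (scores on
the 0–1000 scale are normalised; the boundary is inclusive, which the
upstream "minimum required score" wording suggests but does not state) and
edges supported only by the text-mining channel are dropped. Communities
come from Louvain-style modularity maximisation (igraph's implementation,
seeded for determinism), weighted by the combined score; centralities are
hop-based (degree, pair-counting betweenness with endpoints excluded, and
closeness = reachable count over summed distances, per component, which
keeps it in [0, 1] on disconnected graphs). "Important" nodes are ranked
by the mean of the three per-metric descending ranks — the equal weighting
is a convention, recorded here. The betweenness and modularity routes are
checked in the tests against hand-written exhaustive oracles (path
enumeration; search over all 203 partitions of the six-node two-triangle
graph, whose optimum is exactly Q = 5/14).

# Motif scanning

JASPAR-format count matrices become log2-odds PWMs with a
background-proportional pseudocount of total mass 1 per column. The null
score distribution under the i.i.d. background is computed exactly by
convolving column score distributions on a fixed grid (grain 1e-3 bits);
the threshold for a p cutoff (default 1e-5) is the smallest *achievable*
score whose upper tail is ≤ the cutoff, and scanning scores windows on the
same grid, so thresholds, scores and reported p values are mutually
consistent (an exhaustive-enumeration oracle pins the DP down exactly for
widths ≤ 8). Both strands are scanned via the reverse-complement matrix;
windows containing N are skipped. Promoter windows are [−5000, +1000)
around the TSS, half-open and 0-based (the stated "−5000 to +1000" is
inclusive-ambiguous; the half-open reading gives the 6000-base window used
throughout), strand-oriented and truncation-flagged at contig ends.
Set-level enrichment is the one-sided hypergeometric upper tail on
zero-or-one-occurrence-per-gene hit flags against an explicitly supplied
universe — the de novo discovery tooling and its internal ranking are out
of scope, and no default universe is assumed because the upstream
background set is unstated.

# Coverage metaprofiles

Coverage (bedGraph) is averaged into bins (defaults: ±2000 bp, 100-bp
bins; start-anchored for TSS sets, midpoint-anchored otherwise; these are
conventions of the metaprofile tool family, not stated values), scaled to
reads per million, with minus-strand anchors read 5′→3′. Group differences
are tested by two-sided Mann–Whitney on pooled per-anchor areas — a
pragmatic stand-in, flagged as such, because the upstream claim of
significance names no statistic.

# Synthetic data: the stated world

The generators emulate the designs the pipeline expects, not the full
complexity of real data:

* `simulate_bulk_panel` — six male + six female lines by default, the real
  panel's shape. Log2 expression is Normal (lognormal FPKM; the pipeline
  consumes FPKM, not counts, so a count model would add nothing the code
  ever sees); planted sex effects shift means by ±effect/2; a planted
  module shares a latent factor built to correlate exactly r = 0.85 with
  sex in-sample (the headline module–sex correlation), strong-signal
  defaults effect 4 and noise SD 0.5 on the log2 scale.
* `simulate_cells` — marker structure only: the expressed marker is
  lognormal around 50 FPKM, the silent one zero-inflated (10 % low-level
  leak), each marker independently dropped with probability 0.3 by
  default, a single-cell dropout rate in the realistic range. Under this
  model the expected sexing error on usable calls is leak × dropout ≈ 3 %,
  which is why the ≥ 95 % accuracy criterion is attainable and honest.
* `simulate_promoters`, `simulate_coverage`, `simulate_interactions` —
  i.i.d. backgrounds with planted consensus instances; Poisson bins with a
  multiplicative anchor enrichment; a stochastic block model with scores
  drawn above the 0.7 cut. Null configurations (effect 0, enrichment 1,
  placement 0) are part of the contract and are tested to stay at nominal
  error rates.

Every generator draws from a private, explicitly seeded stream and
restores the caller's RNG state. A green test on this world establishes
that the statistics behave as designed under their own assumptions — it
does not establish anything about library-composition artefacts, strain
effects, batch structure, or single-cell count noise beyond dropout, none
of which are modelled.

# Known limitations

* The dynamic tree cut is approximated by a static quantile cut; very
  nested module structure will be resolved differently than by the hybrid
  algorithm.
* The real accession-based results (the 1624-gene module, the 157
  precursor-stage genes, the 908/148 adult biases, β = 10, the 11 merged
  modules) require the original datasets and are out of scope; the
  acceptance targets are the in-text table statistics instead, and the
  genome-wide conserved counts (36/6/4/30) are *not* reproducible from the
  shipped TF/ERE tables alone (the in-table conserved total is 12).
* Configuration files are JSON; trajectory fixtures, matrices and tracks
  are plain text (TSV/FASTA/BED/bedGraph), small enough to regenerate or
  ship uncompressed.
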