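---
title: "Two-group lncRNA/mRNA array analysis: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-group lncRNA/mRNA array analysis: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncnet)
```

## The analysis model

lncnet implements the standard downstream chain for single-channel
two-group expression arrays in which long noncoding RNAs are profiled
alongside mRNAs. Because lncRNAs are mostly unannotated, the chain ends
in *guilt-by-association*: a lncRNA inherits candidate functions and
candidate transcription-factor regulators from the annotated mRNAs it
is coexpressed with.

The stages and their statistics:

* **Quantile normalization.** Each sample column is replaced by the
  per-rank across-sample means, so all columns share one empirical
  distribution. Ties within a column receive the mean of the rank-means
  they span — deterministic and independent of input row order. Two
  consequences worth knowing: the transform is idempotent and conserves
  the grand mean exactly (to floating tolerance), but the "identical
  multiset" property holds verbatim only for tie-free columns, since a
  tied column's averaged values differ from the raw rank-means.
* **Differential expression.** Fold change is the ratio of linear-scale
  group means, reported as a magnitude ≥ 1 plus a direction — the
  convention in which "down-regulated with FC 7.5" means
  control/case = 7.5. The test is a two-sided unpaired t-test on log2
  intensities: log-normal array noise is approximately Gaussian on the
  log scale, which is also why the synthetic generator works on log2.
  The double cut-off FC ≥ 2 and p ≤ 0.05 (raw p; this screening
  tradition reports uncorrected p-values, and Benjamini–Hochberg is
  available via `bh = TRUE`) defines "dysregulated". Pooled-variance
  Student is the default variant — the classic array-suite default —
  with Welch behind `welch = TRUE`; the test scale can be switched to
  linear via `log_scale_test = FALSE` since vendor pipelines are not
  explicit about it.
* **qPCR concordance.** 2^−ΔΔCt with ideal efficiency 2: per-sample
  ΔCt = Ct(target) − Ct(reference), group means, ΔΔCt = case − control.
  Per-sample ΔCt before group averaging is deliberate: both orders
  agree on balanced complete data, but per-sample degrades gracefully
  when a sample drops its reference measurement. Direction agreement is
  `up ↔ 2^−ΔΔCt > 1`; a relative level of exactly 1 is indeterminate
  and excluded from the agreement fraction rather than counted either
  way.
* **Coexpression edges.** For every lncRNA × mRNA pair, Pearson r
  across all samples pooled and the t-based p on n − 2 df. An edge
  needs |r| ≥ 0.7 *and* p ≤ 0.05; the magnitude reading of the r
  threshold is forced by the existence of negative edges in this kind
  of network. Both gates matter: at n = 6, |r| = 0.7 alone has
  p ≈ 0.12. Pooling case and control samples means the group contrast
  itself contributes correlation — that is intentional, and it is what
  makes the networks condition-specific; `group = "case"`/`"control"`
  restricts to within-group correlation instead. For partner sets used
  in function prediction, `p_only = TRUE` reproduces the looser
  p-only selection some published pipelines use for that step.
* **Enrichment.** Hypergeometric upper tail on gene symbols (probes
  collapse to symbols by set union), computed through `stats::phyper`
  in log space. The universe is the set of gene symbols carried by
  annotated mRNA probes on the array — not the genome — because that
  is the population partner sets are drawn from; it is a `universe`
  argument everywhere. Ranking uses the package-wide total order:
  ascending p, descending overlap/fold-change, ascending id, which
  makes every top-k selection deterministic and permutation-stable.
  "Top 5 TF pairs" is interpreted per lncRNA (a global top-5 would
  yield a 5-edge network, inconsistent with the dozens of TFs such
  networks display).
* **Networks.** Typed graphs (lncRNA/mRNA/TF nodes) with coexpression
  edges weighted by r and TF edges weighted by the enrichment p — each
  edge carries the statistic it was selected by. Exports: SIF (edge
  type as the interaction label, isolated nodes on their own lines),
  edge-TSV and GraphML, the latter two lossless round-trips with
  doubles serialized at 17 significant digits.

## The synthetic generator

`simulate_dataset()` emulates the statistical structure this analysis
assumes, with known ground truth:

log2 intensity = probe baseline + group effect + loading × module
factor + noise, exponentiated to the linear scale. The baseline is
N(8, 1.5²) per probe (typical mid-range log2 signal for single-channel
arrays), the planted group effect puts the full log2(FC) on the case
group so the expected linear group-mean ratio *equals* the planted fold
change, the module factor is one standard-normal draw per sample shared
by all module members, and the noise is N(0, 0.25²) log2 units by
default — a realistic residual scale for well-behaved arrays at this
design size. Two probes with loading λ on the same factor have expected
correlation λ²/(λ² + σ²), i.e. ≈ 0.93 at λ = 0.9, σ = 0.25, safely
above the 0.7 edge threshold. The default design is 3 + 3 samples,
matching the array arm of the emulated study class.

The default planted configuration (`default_sim_config()`) places 8
modules of 2 lncRNAs + 8 mRNAs at loading 0.9 and plants the *whole
module* differentially expressed in the module's direction (FC 4,
modules alternating up/down). Planting only the lncRNAs was tried and
rejected as internally inconsistent: the lncRNA's group contrast then
acts as variance not shared with its partners, pulling pooled |r| to
≈ 0.6 and making the planted partner sets undiscoverable at the 0.7
gate — whereas in real two-group data the coexpression partners of
dysregulated lncRNAs are predominantly the dysregulated mRNAs. A
further 24 lncRNA and 10 mRNA probes carry fold changes 2.5–8 outside
any module, and ~95% of probes are null.

Term and TF collections are sampled without replacement from the mRNA
symbol universe; the designated TF of each module receives ≥ 80% of the
module's mRNA symbols as targets, so TF recovery has a defined truth.
One global seed drives everything through deterministically derived
per-component sub-streams; fixed seed means byte-identical files.

qPCR tables are generated noiseless by default: a planted up-regulation
of fold change F lowers the case-group target Ct by log2 F cycles, so
2^−ΔΔCt recovers F exactly — the identity the qPCR stage is tested
against.

What the generator does **not** emulate: probe-level spatial artifacts,
dye/batch effects, background correction, heavy-tailed outliers,
probe-to-gene multi-mapping beyond simple symbol collapsing, and
correlated null structure. Passing tests therefore demonstrate that the
statistics do what they claim under the assumed log-normal latent-factor
model, not that any particular biological dataset satisfies that model.

## Numerical and degenerate-input choices

* Probes constant in both groups carry no evidence: p = 1 (warned);
  constant in variance but separated in mean: p = 0.
* A constant expression vector has no defined correlation: r = 0,
  p = 1, so such pairs can never become edges; in clustering a constant
  row sits at distance 1 from everything.
* Hierarchical clustering is average linkage on 1 − r over
  row-standardized log2 values; linkage and metric are stated choices
  (vendor heatmap defaults vary and are rarely documented), validated
  against an exhaustive greedy oracle at small n.
* |r| = 1 maps to p = 0 rather than running the t formula into a
  division by zero.
* Enrichment p-values are discrete and therefore conservative
  (super-uniform under the null); calibration tests compare against the
  exact attainable tail values, not a continuous uniform.
* All top-k selections share one total order (p, then magnitude, then
  id), so results are invariant to input row permutations.

## Problem sizes

The bundled validation suite runs the generator at desk scale: 10,000
probes for null calibration of the t-test screen, 500 replicates for
module-edge recovery, 30 replicates for noisy TF-rank recovery, and the
default 300 + 900-probe configuration for end-to-end runs. These sizes
give 3-SE binomial resolution on the calibrated rates while keeping a
full check of the suite in the tens of seconds.

## Known limitations

* The t-test at n = 3 per group leans on log-scale normality; the
  generator satisfies it by construction, real arrays only
  approximately.
* Fold changes computed after quantile normalization are mildly
  compressed when a large fraction of probes is differential, a known
  property of the normalization itself.
* SIF export is lossy by design (no weights or node types); use the
  edge-TSV or GraphML exports for round-trips.
* The pipeline predicts TF association by target-set enrichment; it
  does not model binding, direction of regulation, or motif evidence.
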