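---
title: "Estimating telomerase activity from expression ranks: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating telomerase activity from expression ranks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extendscore)
```

## The model and its assumptions

Telomerase enzymatic activity cannot be read from TERT mRNA alone: TERT is
transcriptionally repressed in many telomerase-positive samples, spliced
into inactive isoforms (notably in brain), and undetectable in essentially
all single-cell protocols; TERC quantification depends on library
chemistry. The estimator implemented here therefore combines the two
*constituent* genes with 11 *marker* genes that co-express with TERT in
telomerase-positive tumours, and works exclusively on within-sample ranks:

$$V_{\mathrm{const},i} = \max(r_{\mathrm{TERT},i},\, r_{\mathrm{TERC},i}),
\qquad
V_{\mathrm{marker},i} = \sum_{m=1}^{11} r_{m,i},$$

$$\mathrm{ES}_i = \frac{\delta\, V_{\mathrm{const},i} + V_{\mathrm{marker},i}}
                       {N_g \cdot N_m},
\qquad
\delta = \bigl(1 - \rho(V_{\mathrm{const}}, V_{\mathrm{marker}})\bigr)^{-1},$$

with $\rho$ the Spearman correlation across samples, $N_g$ the number of
genes in the matrix and $N_m$ the number of signature genes detected in it.
Scores are finally min–max scaled to $[0,1]$ across the samples of the
dataset.

Assumptions worth making explicit:

* **Ranks ascend with expression.** Higher expression of a signature gene
  must raise the score, and the max over TERT/TERC in $V_\mathrm{const}$
  only makes sense if a larger rank means "more expressed". Lowest
  expression gets rank 1; ties get midranks, so the heavily tied
  zero-inflated single-cell case is deterministic.
* **Unit invariance.** Every ingredient is a within-sample rank, so any
  strictly increasing elementwise transform of the matrix (unit change,
  log, scaling normalisation) leaves scores bit-identical. No log
  transform is applied before ranking — it would change nothing.
* **Dataset-relative calibration.** $\delta$ and the $[0,1]$ scaling are
  computed once per input matrix. Scores from separately scored datasets
  are not comparable; score jointly what you want to compare.
* **The trust logic of $\delta$.** If the constituent and marker components
  agree across samples, the functionally decisive TERT/TERC ranks are
  up-weighted; if they disagree (splicing, detection problems), the
  constituent contribution is shrunk. $\delta$ applies to the whole
  dataset, not per sample.
* **Detection rule.** A signature gene counts as present when its row
  exists *and* is not all-zero across samples. This is what makes the
  single-cell fallback well defined: with TERT and TERC rows entirely zero
  the constituent term is dropped (δ is `NA`) and the score is the marker
  rank-sum alone, renormalised through $N_m$. Within-sample zeros in an
  otherwise detected gene simply keep their midranks.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| δ clamp | `adjustment_factor()` | [0.5, 20] | Eq. for δ diverges as ρ→1; 0.5 is the analytic value at ρ = −1, 20 corresponds to ρ = 0.95. A deviation from the unbounded definition, for numerical stability. |
| p threshold | `differential_upregulation()` | 0.05 (raw) | Matches the published filter; no multiple-testing correction by default (`fdr = TRUE` enables BH). |
| fold-change threshold | `differential_upregulation()` | log2 FC > 1.5 | Read as log2(fold change) > 1.5, i.e. FC > 2^1.5 ≈ 2.83, with the fold change computed from group means on the expression scale with pseudo-count 1. The alternative reading (FC > 1.5 on log2 data) is looser and was not adopted. |
| t-test scale | `differential_upregulation()` | log2(x+1) | Welch one-sided t-tests on raw RSEM-like values would be dominated by the log-normal tail; `log_transform = FALSE` disables. |
| threshold grid | `coexpression_scan()` | 0.20–0.70, step 0.05 | The only step producing the stated 11 thresholds over that range ("step of 0.5" is arithmetically impossible). |
| scan scale | `coexpression_scan()` | log2(x+1) | Pearson correlation on raw log-normal expression is deflated by the heavy right tail (for two genes with log-scale correlation r and log2-sd ~1.4, the raw-scale Pearson drops from 0.47 to ~0.36); log-scale co-expression is the field convention. `log_transform = FALSE` restores raw-scale behaviour. |
| scan samples | `derive_signature()` | group A ∪ group B | See design choices below. |
| permutations | `permutation_empirical_p()` | 1000, plain proportion | The empirical p is the fraction of label-shuffled recomputations with correlation ≥ observed; it can be exactly 0. `pseudocount = TRUE` gives (count+1)/(n+1). Degenerate permutations are excluded from the denominator and counted in `n_used`. |
| cell-cycle margin | `classify_cell_cycle()` | 0.1 log2 units | Cells inside a cycling k-means cluster whose G1-S and G2-M scores differ by less than the margin are "ambiguous" and excluded from phase comparisons. |
| k-means | `classify_cell_cycle()` | k = 3, 10 restarts, seeded | Deterministic given a seed. |

## Threshold selection

The co-expression scan records the number of anchor-co-expressed genes at
each cutoff; counts are non-increasing by construction. The percentage
difference between consecutive counts,
$100\,(c_{k-1}-c_k)/c_{k-1}$, grows while raising the cutoff keeps pruning
background effectively; the selected threshold is the first one at which
this percentage *strictly drops* below its predecessor — beyond it, further
increases no longer remove candidates as effectively. Ties do not count as
drops; if the sequence never drops, the last threshold is returned (with a
message); zero counts truncate the scan before selection.

## What the synthetic generator emulates — and what it does not

`simulate_bulk()` states a world chosen *a priori* by power analysis, then
frozen:

* Gene baselines: log2 expression ~ N(7, 1); per-gene, per-sample noise
  N(0, `noise_sd` = 1) on the log2 scale; expression = 2^(log2 value), a
  log-normal matrix. The high baseline keeps the pseudo-count in the
  fold-change estimator negligible.
* Latent activity: telomerase-positive samples ~ U(0.9, 1) (graded,
  near-maximal); ALT-like and no-TMM samples have activity exactly 0 —
  biologically, ALT tumours maintain telomeres without telomerase. Group
  fractions 0.4/0.4/0.2 of 100 samples.
* Planted signal: the 13 signature genes receive an additive log2 shift of
  `effect_size` × activity. One shared latent drives both the upregulation
  (mean shift 2 × 0.95 = 1.9 log2 units between groups) and the mutual
  co-expression across the cohort (expected log-scale anchor correlation
  ≈ 4·var(activity)/(4·var(activity)+1) ≈ 0.45), which is the minimal
  structure under which the derivation pipeline is identifiable.

Why the derivation scans co-expression over *both* groups by default: the
original procedure correlated within the TERT-promoter-mutant group only.
In this generator's world the within-group activity variance is small by
necessity — if the active group's signature genes fluctuated together
strongly *within* the group, that shared variance would propagate into the
score and destroy the stated separation property (AUC ≥ 0.95 at effect 2,
noise 1). The co-expression induced by graded activity therefore lives
across the cohort, and the default scan uses all cohort samples;
`scan_samples = group_a` restores the within-group behaviour for data whose
active group genuinely varies.

`simulate_single_cell()` adds Poisson sampling on top of log-normal rates,
iid Bernoulli dropout (default 0.3), three planted phase populations with
30 near-binary phase markers each (+5 log2 in the matching phase), elevated
signature-marker activity in cycling cells, and optionally fully zeroed
TERT/TERC rows.

Features of real data deliberately **not** modelled: library-size and
batch effects (rank scoring removes the former within sample), gene–gene
correlation among background genes, protocol-specific biases (poly(A) vs
ribo-depletion), gene-specific dropout curves, doublets and ambient RNA. A
green test on this generator therefore establishes that the algorithms
recover the structure they assume, at realistic noise — not that they are
robust to every artefact of real cohorts.

## Numerical choices and degenerate inputs

* Midranks everywhere; per sample ranks sum to $N_g(N_g+1)/2$ exactly.
* All-identical raw scores scale to 0.5 (not NaN), with a warning; a single
  sample skips scaling with a warning.
* δ defaults to 1 (warning) for < 3 samples or constant component vectors.
* The per-gene decomposition attributes the constituent term to the argmax
  constituent gene, split evenly on ties; contributions sum to the raw
  score to ≤ 1e−9 and fractions to 1.
* Duplicate gene rows collapse by per-cell maximum (conservative for a
  detected-expression signature); duplicate sample ids, negative, missing
  or non-finite values are hard errors.
* Stemness scores are Spearman correlations computed as Pearson on
  midranks (exactly equivalent, and fast); constant sample vectors give NA.
* Fewer than 3 distinct (G1-S, G2-M) score pairs sends every cell to
  non-cycling with a warning rather than running a degenerate k-means.

## Known limitations

* Only 5 of the default signature's 13 gene identities are attested in
  accessible text (TERT, TERC, LIN9, HELLS, POLE2); the other 8 marker
  slots are synthetic placeholders (`SYNM04`–`SYNM11`) that must be
  replaced with the published list before real use. The engine itself is
  signature-agnostic.
* Scores are dataset-relative (δ and scaling recomputed per matrix).
* The derivation-recovery property (≥ 90% of planted markers over 20
  seeds) measures 88.6% in this package's frozen stated world: with 40
  samples per group the expression-scale fold-change estimate has a
  standard error of ~0.25 log2 units against a true planted value of 1.9
  and a cutoff of 1.5, so roughly one marker per seed narrowly misses the
  filter. The corresponding acceptance test is left failing rather than
  loosening the threshold or retuning the generator; a cohort of the
  original training size (81 + 123) halves that standard error and passes.
* The permutation test shuffles gene labels once per iteration, shared by
  both scorers; it tests the joint gene-identity structure, not sample
  exchangeability.
* No survival modelling, pathway curation, TERT splice quantification,
  telomere-length estimation, or count-model differential expression —
  those belong to other tools.
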