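# extendscore

Rank-based estimation of telomerase enzymatic activity from gene expression.

## The problem

Telomerase — the ribonucleoprotein that extends telomeric repeats, with
catalytic subunit TERT and RNA template TERC — is reactivated in most
cancers, but its *enzymatic activity* is hard to read off a transcriptome:
TERT mRNA is frequently repressed, alternatively spliced into catalytically
dead isoforms, or simply below detection sensitivity (essentially always in
single-cell data), and TERC lacks a poly(A) tail so its measurement depends
on the sequencing protocol. `extendscore` implements an expression-based
estimator (EXTEND) for analysts who want a per-sample telomerase activity
score from bulk or single-cell expression matrices in any non-negative unit
(RSEM, TPM, RPKM, raw counts): the score is built entirely from
within-sample ranks, so it is invariant under monotone unit changes and
scaling normalisation.

## The score

The 13-gene signature splits into a **constituent** component (TERT, TERC)
and a **marker** component (11 genes co-expressed with TERT but not
functionally tied to telomerase). With `r_gi` the within-sample rank of
gene `g` in sample `i` (ascending, midranks for ties):

    V_const,i  = max(r_TERT,i , r_TERC,i)
    V_marker,i = Σ_m r_m,i                      (over the 11 markers)
    ES_i       = (δ · V_const,i + V_marker,i) / (N_g · N_m)
    δ          = 1 / (1 − ρ),   ρ = Spearman(V_const, V_marker)

`N_g` is the number of genes in the matrix, `N_m` the number of signature
genes detected in it (partially matched signatures renormalise
automatically). δ is computed once per dataset and clamped to [0.5, 20];
scores are then linearly scaled to [0, 1]. When neither TERT nor TERC is
detected (single-cell dropout), scoring proceeds from the marker component
alone. Because δ and the scaling are dataset-level, scores are
dataset-relative: score jointly anything you want to compare.

Beyond scoring, the package ships the full derivation pipeline (one-sided
Welch differential expression with a fold-change filter, anchor-gene
co-expression threshold scan over 0.20–0.70 with percentage-difference
elbow selection, intersection, TERC augmentation), downstream analyses
(stemness index = Spearman correlation of a gene-weight vector with each
sample, gene-label permutation empirical p-values, k-means cell-cycle phase
grouping, pairwise group tests), and a synthetic cohort generator with
planted ground truth used throughout the test suite.

> The shipped default signature (`default_signature()`) carries the five
> attested gene identities (TERT, TERC, LIN9, HELLS, POLE2) plus eight
> clearly labelled synthetic placeholder markers (`SYNM04`–`SYNM11`);
> substitute the published marker list before scoring real data.

## Worked example

```r
library(extendscore)

co  <- simulate_bulk(seed = 42)            # 200 genes x 100 samples,
                                           # telomerase/ALT-like/no-TMM groups
res <- extend_score(co$expr, co$planted_signature)
res
#> EXTEND scores: 100 sample(s), N_g = 200, N_m = 13, delta = 2.793
#>   sample_id raw_score scaled_score n_m_present const_fraction
#> 1      S001 0.9397447    0.9005182          13      0.2080501
#> 2      S002 0.9582592    0.9350989          13      0.2141198
#> ...

round(tapply(res$scaled_score, co$group, mean), 3)
#>        alt       none telomerase
#>      0.224      0.215      0.841

compare_groups(res$scaled_score, co$group)
#>   group1     group2           t      p_value p_bonferroni n1 n2
#> 1    alt       none   0.2939921 7.706733e-01 1.000000e+00 40 20
#> 2    alt telomerase -31.2436737 1.504785e-45 4.514354e-45 40 40
#> 3   none telomerase -21.6880996 1.201965e-19 3.605895e-19 20 40

median(component_contribution(res)$constituent_fraction)
#> [1] 0.1805349
```

The telomerase-positive group scores far above the two
telomerase-negative groups (ALT-like and no-TMM), which are statistically
indistinguishable from each other — exactly the planted structure. The
constituent (TERT/TERC) component contributes ~18% of the score; most of
the signal is carried by the markers, which is what rescues scoring when
TERT/TERC are undetectable.

The same engine drives signature derivation and the CLI:

```sh
Rscript inst/cli/extend simulate bulk --seed 7 --out cohort/
Rscript inst/cli/extend derive --expr cohort/matrix.tsv \
    --group-a a.txt --group-b b.txt --anchor TERT --terc TERC \
    --out derived.json --audit audit.tsv
Rscript inst/cli/extend score --expr cohort/matrix.tsv \
    --signature derived.json --out scores.tsv
```

## Documentation

`vignettes/extend-methods.Rmd` describes the model, its assumptions, every
tunable parameter, what the synthetic generator does and does not emulate,
and known limitations.
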