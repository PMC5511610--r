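---
title: "QTL detection in multi-parent populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTL detection in multi-parent populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mppqtl)
```

## The statistical problem

Nested association mapping (NAM) panels cross one central inbred parent to
a set of peripheral parents and derive doubled-haploid (DH) progeny from
each cross. Mapping QTLs jointly across such crosses raises a modelling
question with no single answer: how many alleles does a QTL carry? This
package implements the single-locus fixed-effect model

y = Xc bc + Xq bq + XQ bQ + r,

where `Xc` holds cross-specific intercepts (absorbing all between-cross
variation), `Xq` optional marker cofactors, and `XQ` the QTL incidence
whose columns depend on the assumed allelic series:

* **parental** — one allele per parent. Entries are the expected number of
  allele copies inherited from each parent (0–2), obtained from a two-state
  hidden Markov model over the flanking markers (identity by descent). In
  a NAM design peripheral-parent effects are nested within crosses, and
  the central parent — the most frequent origin — is the dropped
  reference.
* **ancestral** — one allele per *ancestral group* of parents. Parents are
  clustered at every position from marker similarity in a local window;
  the parental incidence is post-multiplied by the 0/1 ancestral matrix
  `A`, pooling the dosages of parents assumed to transmit the same allele.
  The group containing the central parent is the reference.
* **bi-allelic** — two alleles population-wide: the column is simply the
  minor-allele dosage of the SNP (identity by state), as in GWAS-style
  models.
* **MQE** (multi-QTL-effect) — a multi-locus model in which each QTL
  carries whichever of the three effect types describes it best, built by
  forward selection.

The choice trades parsimony against goodness of fit: complex, diverse
panels favour the parental model; shared effects favour the ancestral or
bi-allelic one, which estimate fewer parameters and gain power from fewer
test degrees of freedom.

The residual `r` is either homogeneous (**HRT**, `R = I s2`) or
cross-specific (**CSRT**, `R = diag(s2_c)` by cross), the latter being
appropriate when the polygenic background differs between crosses (e.g.
when some parent pairs are genetically close and others distant). Crossing
four effect types with two residual structures gives the eight models the
detection pipeline supports.

## Testing, thresholds and detection

At each marker the QTL block is tested with a Wald statistic
`W = bQ' V(bQ)^{-1} bQ` referred to a chi-square with df equal to the
number of retained QTL columns. Columns without within-cross variation are
confounded with the cross intercepts and are pruned (the position is
flagged non-testable when none remain, and its profile score is 0). The
chi-square reference (rather than an F correction) is slightly liberal in
small samples; permutation thresholds absorb this in practice.

Genome-wide significance uses permutation: phenotypes are shuffled
*within cross* (preserving the cross means that the intercepts absorb; a
global shuffle is available), the simple-interval-mapping scan is re-run,
and the threshold is the upper 95% quantile of the per-permutation maximum
scores. Exact CSRT permutation scans are computationally prohibitive, so
thresholds for cross-specific models reuse the corresponding HRT
threshold, and the MQE threshold is the mean of the parental, ancestral
and bi-allelic thresholds (a `max` rule is available as a stricter
variant).

Detection per effect type proceeds as SIM → cofactor selection → two CIM
rounds (cofactors re-selected between rounds, which the procedure's
description leaves open; re-selection lets round-two cofactors profit from
round-one conditioning) → candidate peaks → backward elimination at
α = 0.01. One spacing constant (20 cM, the documented minimum distance
between QTLs) doubles as the cofactor exclusion window around the tested
position, deliberately keeping a single knob.

Explained variance is reported as adjusted R² for HRT models
(`1 - (RSS_full/df_full)/(RSS_red/df_red)`, the reduced model holding only
cross intercepts) and, for CSRT models, as the Cox–Snell likelihood R²
from *maximum-likelihood* (not REML) fits, degrees-of-freedom-adjusted by
`R2 - (df_QTL/df_full)(1 - R2)`.

## The fast CSRT approximation

Refitting the cross-specific variances by REML at every scanned position
is too expensive inside permutation loops and cross-validation. The
**f-CSRT** approximation estimates the per-cross residual variances once,
in the model *without* a QTL term, and holds them fixed during the scan:
each position is then a generalized least-squares fit with known weights,
and `V(bQ)` is the exact `(X' R^{-1} X)^{-1}` block. The exact
per-position REML scan remains available (`residual = "csrt"`); on
simulated data the two agree to Spearman correlation above 0.95 even under
9:1 variance heterogeneity, and f-CSRT reduces to ordinary least squares
behaviour when variances are homogeneous.

The CSRT fitter itself alternates GLS for the fixed effects with
closed-form per-cross variance updates: an EM-type update for REML
(provably monotone in the REML log-likelihood, which the test suite
checks on every fit) and the mean squared residual for ML. Variances are
floored at `1e-8 var(y)` to keep degenerate crosses (e.g. a cross with a
quasi-deterministic phenotype) from producing a singular `R`; convergence
is declared when the relative log-likelihood change drops below `1e-8`
(default cap 200 iterations, with a warning and a flagged fit on
non-convergence). The fitter reproduces `nlme::gls` with a `varIdent`
structure to six significant digits, which the test suite uses as an
independent oracle.

## Cross-validation: explained vs predicted genetic variance

Twenty replications of a fivefold scheme, partitioned *within cross*,
give 100 runs. Per run, detection runs on the training set (TS) and

* `pTS = R2_adj / h2bar` measures the genetic variance *explained* in the
  TS. The population-level heritability `h2bar` is not defined by the
  procedure we follow; we use the cross-size-weighted mean of the
  per-cross heritabilities, consistent with the weighting of the predicted
  counterpart.
* `pVS_c = cor(y_VS, yhat_VS) / h2_c` within each cross, with
  `yhat = X_VS b_TS`; the population-level `pVSbar` weights the per-cross
  values by validation-set cross sizes. Note this convention divides the
  *correlation*, not its square, by h²; values can therefore exceed 1. The
  squared-correlation variant is available (`squared = TRUE`) but is not
  the default, because the printed form is the procedure's definition.

Zero-QTL runs contribute pTS = pVS = 0: a model holding only cross means
carries no within-cross signal. Crosses with fewer than three validation
individuals are skipped with renormalized weights; zero-variance crosses
contribute 0 with a notice. The difference `mean pTS - mean pVSbar`
estimates the optimistic bias of the detection procedure.

## The NAM simulator: what it emulates, and what not

Every stage is testable against a generator with known truth
(`simulate_nam()`):

* **Parents.** `n_ancestral` founder haplotypes drawn Bernoulli(0.5) per
  marker; each parent copies one founder and mutates each marker with
  probability `parent_divergence`. Within-founder-group simple matching
  then has expectation `1 - 2p(1-p)`, so divergence directly controls the
  parental relatedness that the ancestral clustering must recover.
* **Meiosis.** One gamete per DH line, a two-state Markov chain with
  Haldane transition probabilities and no interference — the same model
  the IBD module assumes, which makes the HMM posteriors exact oracles on
  simulator output.
* **Phenotypes.** `y = cross mean + genetic value + N(0, s_c)` per cross.
  The polygenic background and the plot error are collapsed into the
  single cross-specific residual because the analysis unit is an adjusted
  mean, matching the fitted models' residual structure. With an `h2_target`
  the residual SD is scaled per cross as `s_c^2 = var_g,c (1 - h2)/h2`; the
  realized heritability is recorded and becomes the dataset's h². A QTL
  whose effects barely differ within one cross then yields a
  quasi-noiseless cross — a legitimate corner of this stated world that
  the empirical permutation threshold handles, but worth knowing when
  choosing configurations. Alternatively, fixed per-cross residual SDs can
  be supplied directly.
* **Effects.** Parental/ancestral QTLs draw i.i.d. N(0, scale²) diplotype
  effects per parent/founder group; a bi-allelic QTL adds `scale` for the
  allele coded 2. A DH line inherits the effect of its origin parent (or
  `dosage/2 × scale` for bi-allelic loci), so a fitted coefficient on the
  0–2 allele-dosage scale equals *half* the parent-vs-parent substitution
  contrast; the recorded truth includes these model-scale contrasts.

Default configuration: 5 crosses of 72 DH lines (≈360 lines, a typical
NAM subset), 10 chromosomes of 160 cM at 1 cM spacing (a thinned
consensus-map density), 4 founders, 5% divergence, h² target 0.6 (between
typical yield and height heritabilities). The simulator does *not* emulate
genotyping error, segregation distortion, crossover interference,
dominance or epistasis — a green test establishes correctness of the
machinery under the stated model, not robustness to those artefacts.

## Numerical and design choices

* **Map function.** Haldane throughout (`r = (1 - exp(-2d/100))/2`),
  matching the simulator; scan positions are marker positions only (no
  pseudo-marker grid), which is adequate after map thinning and keeps CIM
  bookkeeping simple.
* **Origin HMM.** Genotyping error rate defaults to 1e-3 (configurable);
  uninformative or missing markers emit 1 for both states, so a cross of
  identical parents yields flat 0.5 posteriors rather than an error.
* **Ancestral clustering.** The exact local-similarity/kinship score of
  the original clustering software is not reproduced; windowed simple
  matching (2 cM window, inclusive bounds) with average-linkage merging
  and a 0.9 similarity threshold is a declared, swappable strategy — the
  downstream contract is only a per-position parent→group map. Merge order
  is deterministic (highest similarity first, ties by lexicographic
  member pair). An empty window falls back to the nearest marker with a
  notice.
* **Imputation.** Missing dosages are imputed by the within-cross mode
  (population mode as fallback) instead of haplotype phasing: after
  standard filtering missingness is ≤10%, and determinism keeps analyses
  reproducible. Declared as a deviation from haplotype-based imputation.
* **Marker preprocessing.** MAF is computed over non-missing offspring
  only (parents carry no segregation information); co-located markers
  (equal position after rounding to 1e-6 cM) keep the highest-MAF
  representative, ties by marker id; thinning bins are `[k·bin, (k+1)·bin)`
  per chromosome with ties by position then id.
* **Ties in peak selection** break by lower chromosome, then lower
  position; tied MQE candidates by higher score, then chromosome and
  position. MQE forward selection is capped at 20 steps as a safety net
  and finishes with an optional (default on) backward elimination.
* **Permutations** default to within-cross shuffling; thresholds need at
  least 20 permutations (quantile unstable below), 1000 recommended.

## Known limitations

Support intervals (LOD-drop), multi-trait scans, random-effect QTL models
and kinship/GRM polygenic terms are out of scope. The Wald/chi-square
reference is liberal for very small crosses. The acceptance-style test
suite runs its Monte-Carlo checks at reduced scale (e.g. 100 null
datasets with 100 permutations for the type-I calibration check) with
intervals recomputed at the size actually used, so they bound the
behaviour more loosely than a production-scale study would.
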