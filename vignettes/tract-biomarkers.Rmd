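---
title: "From FA tract statistics to obesity biomarker matrices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From FA tract statistics to obesity biomarker matrices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatract)
```

## The problem

Diffusion tensor imaging summarizes the microstructural coherence of white
matter in the fractional anisotropy (FA) map, a scalar in [0, 1] per voxel.
Group studies usually compare FA voxelwise or along skeletonized tracts;
`fatract` instead works at the level of whole-tract summary statistics and
asks which of them, jointly, can predict a subject's obesity status. The
pipeline has two halves:

1. **Screening.** For each tract of an integer label atlas (the package
   ships the 50-tract ICBM-DTI-81 white-matter parcellation) and each
   statistic of a 12-statistic panel, one *tract measurement* per subject
   is computed — 600 columns in the default design. A measurement is kept
   as a candidate when it (a) differs between the normal-weight (NW,
   19 ≤ BMI < 25 kg/m²) and overweight/obese (OB, BMI ≥ 25) groups by a
   Wilcoxon rank-sum test at p < 0.05, and (b) correlates with BMI across
   the whole cohort by Spearman's ρ at p < 0.05 after Benjamini–Hochberg
   FDR correction. The number of surviving columns is called N.
2. **Model building.** From the N candidates, a randomized add/exclude
   stepwise search builds two ordinary-least-squares models: a BMI
   quantification model scored by Pearson correlation, and an NW/OB
   classifier on −1/+1 labels scored by accuracy at a 0 threshold. The
   final coefficients, laid out on the tract × statistic grid together
   with the model constant, are the *biomarker matrices*: applying a
   biomarker to a subject is an element-wise product summation plus the
   constant.

## The statistic panel

Thirteen descriptive statistics are implemented: arithmetic mean, median,
standard deviation, range, variance, harmonic mean, geometric mean,
interquartile range, maximum, minimum, mean absolute deviation, median
absolute deviation, and root mean square. The default panel keeps twelve,
dropping the mean absolute deviation, so that the canonical 600 = 50 × 12
column count holds; any subset of the thirteen can be selected instead
(`panel =` everywhere). Conventions are fixed for reproducibility: sample
(n−1) denominators for variance and SD, linear-interpolation (type 7)
quartiles for the IQR, and the unscaled `median(|x − median(x)|)` for the
median absolute deviation. The harmonic and geometric means are undefined
at zero and FA maps contain exact zeros, so for those two statistics only,
non-positive voxels are dropped before computation; a tract with no
positive voxels yields a missing value. Empty tracts yield missing values
across their columns, and such columns are flagged out of screening with a
logged count rather than failing the run.

## Screening details

Three choices are deliberate and documented rather than implied:

* **The FDR family is the full set of non-flagged measurement columns**
  (600 in the default design). The correction is applied to the
  correlation analysis as a whole; a `screening_result` records the family
  size actually used.
* **Condition one is uncorrected.** Only the Spearman p-values are
  FDR-adjusted; the rank-sum condition uses its raw p-value. Both
  conditions use strict `< alpha`.
* **Rank-sum p-values are hybrid.** With both groups of size ≤ 8 the null
  is enumerated exactly over all group assignments of the pooled midranks
  (`P(|W − μ| ≥ |w − μ|)`); larger groups use the tie-corrected normal
  approximation with a 0.5 continuity correction, which at the default
  80-vs-80 comparison is accurate to well under a percent. The crossover
  is configurable (`exact_max`).

Spearman's ρ is computed as the Pearson correlation of midranks with a
two-sided t approximation on n − 2 degrees of freedom; constant columns
have no defined ρ and are flagged and excluded.

## Cohort split

Before any model is built the cohort is partitioned into training,
validation and testing subsets (default 80/40/40) so that each integer-BMI
stratum is spread across subsets: a stratum of c subjects sends
⌊c/2⌋–⌈c/2⌉ to training and splits the remainder between validation and
testing with |val − test| ≤ 1 — the "2:1 when possible" rule. Exact global
sizes are reached by a two-phase seeded draw: odd strata are randomly
chosen to round their training share up, then odd remainders are randomly
assigned their extra subject to validation or testing. For size triples
that cannot satisfy both constraints a randomized repair pass relaxes the
stratum rule; the default sizes never need it. BMI is rounded to the
nearest integer for stratification only.

## The add/exclude search

Each restart starts from one uniformly drawn candidate, whose
train/validation score pair initializes the incumbent best mean score.
The search then alternates:

* **ADD, k = 1…5:** the pool of unused candidates is shuffled once and
  swept in disjoint consecutive k-subsets; each subset is tentatively
  added and the model refit on the training rows. A candidate model is
  accepted only if its mean score *strictly* exceeds the incumbent's; ties
  never advance the search. On acceptance the sweep restarts at ADD k = 1
  with a fresh pool; rejected candidates stay out of consideration only
  until the next accepted step.
* **EXCLUDE, k = 1…5:** once all ADD levels are exhausted, k-subsets of
  the incumbent's own features are tentatively removed under the same
  accept rule; an acceptance returns to ADD k = 1.

A restart terminates when a full pass over both phases produces no
acceptance, which makes the incumbent's mean-score trace strictly
increasing by construction. The whole procedure is repeated for 1,000
independent restarts by default (`search_config()`), each seeded as
`seed + restart`, and the best incumbent wins; ties keep the earliest
restart, so results are exactly reproducible.

The disjoint-partition sweep costs O(N/k) fits per level rather than all
C(N, k) combinations, which is what makes 1,000 restarts affordable; a
`full_sweep` flag enumerates every k-subset instead and is used by the
exhaustive-oracle tests on 6-candidate problems. Other numerical choices:
fits use the minimum-norm least-squares solution via the SVD, so
collinear or duplicated columns cannot produce unstable results; a score
of exactly 0 classifies as NW (a measure-zero event, fixed for
determinism); prediction vectors with zero variance score −∞ so a
degenerate model can never be accepted; and model size is capped at
n_train − 2 to keep the fit over-determined, with larger candidate subsets
treated as non-improvements.

## Evaluation conventions

Regression reports per subset: Pearson r with the Fisher-z 95% interval
`tanh(atanh(r) ± 1.96/√(n−3))` and the two-sided t p-value, RMSE and MAPE
against actual BMI, and Bland–Altman agreement where differences are
predicted − actual, the reproducibility coefficient is RPC = 1.96 × SD of
the differences, and the coefficient of variation is 100 × SD over the
mean of the paired means (the standard Bland–Altman CV; other CV
definitions exist, and this one is stated explicitly because nothing in
the outputs pins it otherwise).

Classification reports sensitivity (OB = +1 is the positive class),
specificity and accuracy per subset. Their RMSE and MAPE follow the ±1
label convention: errors are computed between the −1/+1 actual labels and
the hardened predicted labels over the rows of the respective metric, so a
misclassified subject contributes an error of magnitude 2 and the closed
forms RMSE = 2√(1 − rate) and MAPE = 200(1 − rate)% hold. This convention
is a reverse-derived assumption pinned by worked examples in the test
suite; it is the only reading we found that reproduces a published table
of rates and errors cell for cell (one cell of that table disagrees with
the closed form by more than rounding and is excluded from testing).

## The synthetic cohort generator

`generate_cohort()` produces the study conditions the pipeline assumes,
so every stage is testable without imaging data:

* **Cohort shape.** 80 NW subjects with integer BMI uniform on 19–24 and
  80 OB subjects on 25–47, the OB side split exactly 49/19/12 across the
  25–29/30–34/35–47 bands (uniform within band) to mimic the decreasing
  tail of a general-population sample.
* **Matrix mode** (default test path): each column j is
  x_ij = μ_j + β_j (BMI_i − mean BMI) + ε, ε ~ N(0, noise_sd²), with
  β_j = 0 off the planted columns. Defaults plant 10 of the 600 columns at
  β = ±0.003 FA-units per kg/m² with noise_sd = 0.02, i.e. a per-column
  Spearman correlation with BMI near 0.6 — strong enough to be screened
  reliably, far from noiseless. μ_j is drawn once per cohort from
  U(0.3, 0.6).
* **Image mode:** small FA volumes (24³ by default) over a block atlas of
  disjoint 4³ cubes, voxel FA drawn from a Beta distribution with
  concentration κ = 50 whose mean shifts linearly with BMI in planted
  tracts. This exercises the NIfTI I/O and statistics stages end to end;
  effects reach screening through the computed tract statistics.

What the generator does **not** emulate: spatial correlation between
voxels and tracts, anatomy and registration error, scanner and site
effects, the correlation structure among statistics of the same tract
(matrix-mode columns are independent given BMI), and any confounding of
BMI with other subject variables. Passing tests therefore demonstrate
that the pipeline's machinery is correct and recovers planted structure
under its own assumptions — not that comparable performance is attainable
on real imaging data.

## Problem sizes used by the tests

The suite checks oracle equivalence on ≥100 random instances per
primitive; the exhaustive search oracle uses 20 problems of 6 candidates
(63 subsets each) against 200-restart searches; parameter recovery runs
the full default cohort (160 × 600, 10 planted columns) with 100-restart
searches; the image-mode recall property uses 20 cohorts of 80 subjects.
The acceptance script runs the complete pipeline at the paper-scale 1,000
restarts. These sizes were chosen to make the checks statistically
meaningful while keeping a full run in minutes on one CPU.

## Limitations

The package reproduces a model-building construction, not a clinical
claim: biomarker matrices learned on one cohort carry that cohort's
demographics and acquisition with them. The stepwise search optimizes the
mean of training and validation scores, so the validation subset
participates in selection and only the untouched testing subset gives an
unbiased estimate. OLS on ±1 labels is a linear discriminant, not a
calibrated classifier. The search is a randomized heuristic: restarts
make finding the global best-subset likely on small candidate sets, but
nothing guarantees it in general.
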