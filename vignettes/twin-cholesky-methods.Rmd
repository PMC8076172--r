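---
title: "Methods: bivariate Cholesky twin modelling in twinchol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bivariate Cholesky twin modelling in twinchol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

twinchol decomposes the variance of a phenotype measured at two occasions
("visits") in monozygotic (MZ) and dizygotic (DZ) twin pairs into
additive-genetic (A), shared-environment (C) and unique-environment (E)
components, using the bivariate Cholesky structural model. This vignette is
the package's own account of the model, its numerical choices, and what its
synthetic-data generator does and does not emulate.

## The model

Each variance component loads on the two visits through a lower-triangular
2x2 factor; for A the paths are $a_{11}$ (visit-1 loading), $a_{21}$
(the visit-1 factor carried into visit 2) and $a_{22}$ (a factor specific to
visit 2), and analogously $c_{..}$, $e_{..}$. The component covariance
matrix is the outer product $LL^\top$, which is positive semidefinite for
*any* real paths — the reason this parameterisation is standard for
optimisation. The expected covariance of the observation vector
(twin1 visit1, twin1 visit2, twin2 visit1, twin2 visit2) has within-twin
blocks $A + C + E$ and cross-twin blocks $kA + C$, with $k = 1$ for MZ and
$k = 1/2$ for DZ pairs — the universal twin-design sharing coefficients.
Dominance is deliberately not modelled; with only MZ/DZ pairs reared
together, C and D cannot be estimated jointly, and the twin-correlation
pattern this package targets (MZ correlations below twice the DZ
correlations) points to ACE-family models.

Phenotypes are analysed on the natural-log scale (`log_transform_phenotype()`).
The base is immaterial for every standardized quantity the package reports;
natural log is used because no convention dictates otherwise.

Derived statistics are closed forms in the paths: visit-specific
heritability $h^2_{v1} = a_{11}^2 / (a_{11}^2 + c_{11}^2 + e_{11}^2)$ and
$h^2_{v2} = (a_{21}^2 + a_{22}^2) / V_2$; the visit-2 *specific* (novel)
heritability $a_{22}^2 / V_2$; component cross-visit correlations such as
$r_g = a_{11}a_{21} / \sqrt{a_{11}^2 (a_{21}^2 + a_{22}^2)}$; the
model-implied phenotypic tracking correlation
$r_{ph} = (a_{11}a_{21} + c_{11}c_{21} + e_{11}e_{21}) / \sqrt{V_1 V_2}$;
and the difference-score (visit 2 minus visit 1) decomposition obtained by
applying delta weights $(-1, +1)$:
$V_X(\Delta) = (x_{21} - x_{11})^2 + x_{22}^2$. A correlation whose
component has zero variance at either visit is reported as `NA`
("undefined"), never as 0 or 1 — both are misleading at that boundary.

## Likelihood and missing data

The likelihood is full-information maximum likelihood (FIML): each pair
contributes the multivariate-normal log density of exactly the entries it
was observed on, using the sub-matrix of the expected 4x4 covariance and
sub-vector of expected means selected by its observation pattern. A
singleton therefore contributes the within-twin 2x2 (or 1x1) marginal, and
a pair with nothing observed contributes zero. Pairs are grouped by
(group, zygosity, pattern) once per dataset, so a deviance evaluation costs
one Cholesky factorisation per distinct pattern rather than per pair.

The means model has per-visit intercepts, group-specific in multigroup
fits. Covariates (mean arterial pressure, stem `"map"`) enter the means
model as per-visit regression coefficients shared across twins: modelling
the covariate inside the likelihood is consistent with FIML under missing
phenotypes, whereas pre-residualising would silently drop incomplete
observations; residualisation remains available to the user as a manual
sensitivity path by transforming the table before fitting.

## Optimisation

`fit_cholesky()` minimises the deviance with quasi-Newton BFGS and
numerical gradients (relative tolerance 1e-12, followed by a polishing
second pass), starting from moment-based values: visit-wise individual
variances split equally between A and E, cross paths at a tenth of the
within scale. When C is free its paths start at a *small non-zero*
multiple of the phenotype SD (0.2 for diagonals, 0.05 for the cross path):
the deviance is an even function of each Cholesky factor column, so an
exact zero start for a component is a stationary point from which a
gradient-based optimiser would never move, and an ACE fit started at
$c \equiv 0$ would silently collapse onto AE. Parameter vectors whose
implied pair covariance has an eigenvalue below 1e-10 are rejected with a
large penalised deviance, keeping line searches inside the feasible region.
Each Cholesky factor's column signs are unidentified; fits are reported
after reflecting columns so diagonal paths are non-negative, which leaves
every covariance and derived statistic unchanged. Perturbed restarts (up
to 5, seed-controlled) are attempted automatically if the optimiser reports
non-convergence, and `n_starts` requests extra multistarts explicitly.

## The model ladder and multigroup tests

`model_ladder()` runs the standard nested sequence: ACE vs AE, ACE vs CE
(3 df each), AE vs E (3 df); the most parsimonious model not significantly
worse at level `alpha` (default 0.05) is selected, preferring the lower
deviance when both AE and CE survive. Within the selected model the
cross/specific paths `e21`, `a21`, `a22` are each tested at 1 df and
dropped when non-significant. Likelihood-ratio statistics are referred to
standard chi-square distributions throughout, *including* for variance
components whose null value sits on the parameter-space boundary (e.g.
$a_{22} = 0$, which enters the covariance only through $a_{22}^2$). The
standard reference is conservative there — the asymptotic null is a
mixture with mass at zero — and the package follows the conventional
twin-analysis practice rather than mixture corrections; its null
calibration tests therefore expect rejection *at or below* the nominal
rate for boundary tests and at the nominal rate for interior ones
(e.g. $e_{21} = 0$).

`fit_multigroup()` compares a heterogeneous model (all paths and means per
group, fitted as independent per-group optimisations, since the deviance is
additive without cross-group constraints) against a homogeneous model with
paths equated across groups. Intercepts stay group-specific in the reduced
model: mean differences between ethnicity/sex groups are established
elsewhere (the descriptives), and the homogeneity question targets the
variance structure. The test has df = (groups − 1) x free paths.
Opposite-sex DZ pairs have no pair-level sex and are excluded, with a
message, from sex-grouped analyses; they participate in pooled and
ethnicity-only analyses.

## Profile-likelihood intervals

`profile_ci()` inverts the likelihood-ratio test: a bound is the value of
the derived quantity at which the profiled deviance rises above its
minimum by the $\chi^2_1$ quantile (3.84 at 95%). For variance-fraction
quantities the constraint is imposed *exactly*: one pivot path is solved
from the target and the remaining parameters (e.g. for
$h^2_{v1} = t$, $a_{11}^2 = \tfrac{t}{1-t}(c_{11}^2 + e_{11}^2)$), and the
rest are re-optimised — no penalty stiffness, warm-started along the
search path, bisection to a 0.0015 tolerance on the fraction scale.
Correlation-type quantities, which lack a clean pivot, use a quadratic
penalty profile instead. Searches respect natural boundaries (fractions in
[0, 1], correlations in [−1, 1]); when the deviance never reaches the
cutoff before a boundary the bound is reported at the boundary and flagged
one-sided, which is the honest summary for, say, a heritability whose
lower limit is zero.

## The synthetic cohort generator

`simulate_twin_cohort()` is the generative mirror of the model:
unit-variance latent factors per factor column, A shared exactly by MZ
co-twins and with correlation 0.5 by DZ co-twins (realised as
$\sqrt{0.5}\,A_{pair} + \sqrt{0.5}\,A_{twin}$), C shared within pair, E
independent per twin; phenotypes are path-weighted sums plus means,
exponentiated onto the raw scale so the canonical CSV exercises the
log-transform step end to end. Missingness is MCAR per entry at per-visit
rates; singletons are generated as pairs with the co-twin removed. One
master seed drives deterministic per-group streams.

`reference_config()` packages the study conditions the rest of the package
is tested against: a bi-ethnic youth cohort (EA: 46 MZ, 75 DZ pairs, 47
singletons; AA: 25 MZ, 59 DZ, 40 singletons; same-sex pairs only, sexes
split 52/48 and 59/41 female) with the best-fitting AE structure —
standardized components $a_{11}^2 = 0.62$, $a_{21}^2 = 0.16$,
$a_{22}^2 = 0.19$, $e_{11}^2 = 0.38$, $e_{21} = 0$, $e_{22}^2 = 0.65$,
unit log-scale phenotypic variance at both visits. Log-scale means are set
so geometric-mean phenotypes sit near 7.1 and 7.6 m/s. The MAP covariate
is generated (mean 80 mmHg, SD 8) with zero effect by default, so the
adjustment machinery can be exercised under a null; non-zero effects are a
config away. Default missingness is zero, matching a cohort whose
descriptive table shows equal Ns at both visits.

What the generator does **not** emulate: age trends within visit,
assortative mating, gene-environment interaction or correlation,
opposite-sex pairs, informative dropout, and measurement error beyond E.
Passing tests therefore certify the estimator under the model's own
assumptions — a parameter-recovery claim — not robustness to the ways real
cohorts violate them. Note also that a unit log-scale variance is far
larger than a realistic biological CV; the generator standardizes scale
because every reported quantity is scale-free.

## Simulation sizes and numerical tolerances in the test suite

Chosen once, as a balance between Monte-Carlo error and a test suite that
stays pleasant to run:

* recovery of the standardized components: 200 replicate cohorts of
  200 MZ + 200 DZ complete pairs (mean estimates have SE ≈ 0.004–0.005,
  comfortably inside the ±0.02 assertion bands);
* null calibration of path LRTs and profile-interval coverage: 200
  replicates of 100 MZ + 100 DZ pairs, a cohort-realistic scale;
* generator moment checks: 50,000 pairs per zygosity, where sample
  covariances are expected within 0.01 of their targets;
* ladder selection consistency: 50 replicates of 1,000 + 1,000 pairs;
* exact identities (double-entry symmetry, MZ−DZ cross-covariance = A/2,
  fraction normalisation, sign-flip invariance) are asserted at 1e-10 to
  1e-14.

## Known limitations

* Two visits only; no triplets or higher-order multiples; no sex-limitation
  (qualitative or quantitative) models; no D component.
* Boundary LRT p-values are conservative, as discussed above.
* The homogeneity test equates paths, not means; a means-heterogeneity
  test is outside the package's scope.
* Profile intervals for correlation quantities rely on a penalty profile
  whose constraint is enforced to about 1e-3 on the correlation scale.
* The double-entry Pearson twin correlation is one declared choice among
  defensible estimators (single-entry Pearson, intraclass); values can
  differ slightly between conventions, so tables produced here should name
  the estimator when compared across studies.
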