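---
title: "Methods: path-analytic mediation of early-adversity effects on brain structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: path-analytic mediation of early-adversity effects on brain structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainpath)
```

`brainpath` implements a three-stage observational analysis that links
childhood maltreatment (CM) to adult regional brain structure through adult
trauma (AT), body-mass index (BMI) and C-reactive protein (CRP), together
with a synthetic-cohort generator that makes every stage testable without
restricted data. This vignette is the package's own account of the science:
the models and their assumptions, the generator and what it does and does
not emulate, and the numerical decisions inside the estimator.

## 1. The statistical models

### Cohort-level path model (H1)

The four observed variables are analysed on a standardized log scale (see
Section 3). The hypothesis model is recursive (acyclic, diagonal residual
covariance):

$$\mathrm{BMI} = a_1\,\mathrm{CM} + e_1,\qquad
  \mathrm{AT} = a_3\,\mathrm{CM} + e_3,$$
$$\mathrm{CRP} = a_2\,\mathrm{CM} + b_1\,\mathrm{BMI} + b_2\,\mathrm{AT} + e_2 .$$

Because `bmi` and `at` each have a single parent, $a_1$ and $a_3$ are simple
regression coefficients; the three paths into `crp` are partial
coefficients. With four variables there are ten unique second moments and
nine free parameters (five paths, four variances), so the model is
over-identified with one degree of freedom — the omitted BMI–AT residual
covariance. We deliberately leave that covariance out: the hypothesis
diagram contains no such edge, and an over-identified model is what makes
the fit indices informative. A saturated variant can be fitted by adding the
edge through `path_model()` if a user wants the df = 0 check.

Estimation minimizes the maximum-likelihood discrepancy
$$F_{ML}(\theta) = \ln|\Sigma(\theta)| + \mathrm{tr}\,(S\,\Sigma(\theta)^{-1})
  - \ln|S| - p,$$
with $\Sigma(\theta) = (I-B)^{-1}\Psi(I-B)^{-T}$. For recursive models with
diagonal $\Psi$ the minimizer coincides with per-equation least squares;
the optimizer therefore warm-starts at the least-squares solution computed
from the moments and runs quasi-Newton (BFGS, analytic gradient) only if the
gradient norm still exceeds $10^{-10}$, erroring if it cannot reach
$10^{-6}$ within 500 iterations. The test suite checks the
ML-equals-least-squares identity against `lm()` on random recursive models
at $10^{-8}$, and checks that random perturbations of the solution never
decrease $F_{ML}$.

Inference is robust to non-normality, which matters because the
log-transformed scores remain skewed: sandwich (Huber–White) standard errors
are built from the empirical fourth-moment matrix $\Gamma$ of the unique
products $x_ix_j$, and the test statistic is mean-scaled,
$T_{SB} = T_{ML}/c$ with $c = \mathrm{tr}(U\Gamma)/df$ for the standard
residual weight matrix $U$. We use $T = (n-1)\,F_{ML}$ with $S$ the unbiased
sample covariance. Wald $z$ is estimate over robust SE, with two-sided
normal p-values; products of coefficients along a chain (indirect effects)
get delta-method errors from the robust parameter covariance, which reduces
to the Sobel formula for two-edge chains with uncorrelated components. The
large samples involved justify normal-theory inference on the products, so
no bootstrap is used.

Fit indices follow the conventional definitions — CFI against the
independence baseline, RMSEA with a 90% noncentral-$\chi^2$ confidence
interval, SRMR as the RMS of standardized residual moments over all unique
elements (diagonal included) — with the usual qualitative bands (CFI good
> 0.97, acceptable 0.95–0.97; SRMR good < 0.05, acceptable 0.05–0.10; RMSEA
good < 0.05, acceptable 0.05–0.08). "Robust" variants plug the scaled
statistics into the same formulas. The population-corrected family of
robust indices is a reasonable alternative; the plug-in form was chosen for
transparency and both are reported side by side when present.

### Regional maps (H2)

Each region is regressed on one predictor at a time (`region ~ bmi`,
`~ crp`, `~ at`, plus `~ cm` as a negative control); the three maps
intentionally do not adjust for one another — their purpose is to establish
that each adult variable independently relates to brain structure.
Multiplicity is controlled by BH-FDR at 5% with the family equal to the
number of analysed regions (a region whose data are missing or degenerate
drops out of the family and is reported missing, never zero). Pairs of
cortical t-maps are compared by Spearman correlation, with significance
assessed by a spin test: a uniformly random 3D rotation is applied to all
parcel centroids, each rotated centroid takes the value of its nearest
original parcel (ties to the lowest index; assignments may duplicate), and
the two-sided p-value is $(1 + \#\{|\rho_{null}| \ge |\rho_{obs}|\})/(S+1)$.
This centroid-based variant is the standard choice for parcellated maps;
it differs from vertex-level spin tests in granularity. Because the maps
are already symmetrized, a single sphere is rotated and no left/right
mirroring step exists. The default is $S = 10{,}000$ spins, enough to
resolve p-values near $10^{-4}$; one- versus two-sided conventions are a
genuine free choice and we fix the two-sided form.

### Region-wise nested mediation models (H3)

At each region the five-variable *full* model adds direct effects of BMI
($c_1$), CRP ($c_2$) and AT ($c_3$) on the region (eight paths), while the
*sparse* model keeps only $c_2$ (six paths): any BMI or AT influence must
then ride through CRP. Both are fitted with robust errors and compared with
the Satorra–Bentler scaled difference statistic, $k = 2$; a non-positive
difference-scaling $c_d$ (a known pathology of the mean-scaled difference
test) falls back to the unscaled difference with a warning rather than
producing a negative statistic. Contrast p-values are corrected across
regions with BH-FDR by default; Holm FWER is available through
`contrast_correction = "holm"` since both conventions are defensible for a
region-selection step, and the choice is recorded in the result object.
Indirect chains (e.g. $a_1 c_1$ for CM→BMI→region, $a_1 b_1 c_2$ for
CM→BMI→CRP→region) are estimated exclusively in the regions where the
chain's host model won, then FDR-corrected within each chain's evaluated
set. Regions where either fit fails are labelled unevaluated. The Wald $z$
of a chain is the delta-method $z$ of the product; the product of the
component $z$'s is not used.

## 2. The synthetic-data generator

The generator defines the population the tests live in, so its defaults are
fixed once, from published summary statistics, and are not tuning knobs:

* **Structural coefficients** (standardized): $a_1 = 0.072$, $a_2 = 0.008$,
  $a_3 = 0.315$, $b_1 = 0.434$, $b_2 = 0.019$ for the imaging-sample
  (`variant = "mri"`, n = 21,738) configuration; the replication
  configuration (`variant = "ukb"`, n = 116,887) changes $a_2$ to 0.0095.
  Residual SDs are solved so every structural latent has unit variance,
  which makes the configured coefficients exactly the standardized ones the
  pipeline should recover; zero residual SDs are allowed as a noise-free
  limit.
* **Marginals**: BMI 26.5 (4.2) kg/m² and CRP 2.03 (3.53) mg/L are
  lognormal with `meanlog`/`sdlog` solved from the target mean/SD — strictly
  positive, right-skewed, and exactly invertible by the pipeline's log
  transform. CM is an integer questionnaire sum in [0, 25] produced by a
  censored lognormal count map
  $\mathrm{count}(z) = \min(25, \mathrm{round}(e^{\max(0,\mu+\sigma z)}-1))$
  whose $(\mu, \sigma)$ are solved by quadrature to hit mean 1.70, SD 2.31;
  the ramp produces the heavy zero inflation typical of trauma screeners.
  AT targets mean 1.93, SD 2.37 via a lognormal: it is kept *continuous*
  rather than integer because the structural model is defined between the
  analysis-scale (standardized log) variables, and an integer rounding of AT
  would make the analysed `log1p(at)` a non-affine transform of the latent,
  attenuating the recovered $a_3$ and $b_2$ by a few percent — a bias, not
  noise. CM can stay discrete because it is exogenous: the downstream
  coefficients are defined *from* the standardized `log1p(cm)` scale, so the
  discreteness propagates consistently. Accordingly the default log
  conventions are `log1p` for CM and `log` for AT/BMI/CRP (both are config
  switches).
* **Covariates**: age (truncated normal, 55 ± 7 years on [40, 70] —
  the recruitment window of the emulated cohort), sex (54% female), a
  Townsend-like SES index (−1.94 ± 2.69, truncated to [−6, 10]) and a
  3-level site label. Effects are injected on the log scale *before*
  exponentiation as $z^* = \sqrt{1 - v_\gamma}\,u + \gamma^\top c$, which
  keeps the marginal calibration on target and makes the pipeline's
  residualize-after-log order exactly correct in the synthetic world.
  Defaults are modest (e.g. age +0.10 on log-BMI and log-CRP, SES +0.10 on
  log-AT, age −0.20 and site offsets on regions); the dependence of CM on
  covariates is not published, so it defaults to zero but is configurable.
* **Geometry and regional effects**: cortical parcels are a Fibonacci
  lattice on the unit sphere (180 by default) plus 7 named subcortical
  structures without centroids (exempt from spins). Effect maps and the
  per-participant noise field are Gaussian-process draws under a
  squared-exponential kernel in chordal distance (default length 0.3,
  roughly the nearest-neighbour spacing of a 180-parcel sphere; 0 gives
  independent regions). The BMI and CRP maps are two noisy copies of one
  shared smooth map (mixing noise 30%), reproducing the observed regime in
  which the BMI and CRP cortical maps are very highly correlated. The AT
  cortical map is much weaker (SD 0.008, anticorrelated with the shared map,
  weight −0.4): with ~180 cortical tests at n ≈ 21,700, that scale implies
  only an isolated significant AT area, matching the reported sparsity of
  cortical AT effects, and keeps the CM control map null. Subcortical
  defaults are BMI +0.02, CRP −0.025, AT −0.03, mirroring the reported
  direction pattern (BMI increases, CRP/AT decrease subcortical volume).
  Regional values are mapped to thickness-like units (2.6 ± 0.16 mm) for
  cortex and volume-like units (5000 ± 450) subcortically.
* **Missingness and outliers**: an optional completely-at-random cell mask,
  and `inject_outliers()` which displaces cells to median ± m·MAD
  (m > 5 enforced — smaller displacements would be undetectable by the
  5-MAD filter by construction) with the planted indices returned as ground
  truth.

Everything derives deterministically from the master seed (`withr`-scoped,
cohort at `seed`, brain at `seed + 1`), and every written table carries the
seed and a configuration hash in a `#` comment header.

What the generator does **not** emulate: selection and eligibility effects,
genuinely ordinal questionnaire items (AT is continuous), site-specific
scanner artefacts beyond additive batch offsets, motion or coil covariates,
non-random missingness, and any nonlinearity in the structural relations.
Passing tests therefore demonstrate that the pipeline recovers the
parameters of a linear-Gaussian-on-the-log-scale world with realistic
marginals and spatial autocorrelation — not that the published effect sizes
are correct in the real cohort.

## 3. Preprocessing

The analysis-ready variables are produced in a fixed order: log transform
(`log` for positive measures, `log1p` for zero-inflated sums, with the
offending row named when a nonpositive value meets plain `log`), then the
regional 5-MAD mask, then nuisance regression, then z-scoring. The MAD is
the *raw* median absolute deviation — no 1.4826 consistency constant —
because the exclusion rule is stated in plain MAD multiples; the constant is
exposed as an argument. A zero MAD excludes nothing. For a standard normal
variable the rule removes the fraction $2(1-\Phi(5\cdot 0.6745)) \approx
7.5\times10^{-4}$, which the suite verifies against that closed form.
Bilateral homologues are averaged when hemisphere-specific data are given;
if one side is masked the other side's value is used alone (maximizing
retained data; dropping the cell instead is the documented alternative).
Nuisance designs are age, sex, age×sex and SES for phenotypes, plus site
indicators for regional data; residuals are exact least-squares residuals
(orthogonal to the design at $10^{-8}$, idempotent at $10^{-10}$), and
rank-deficient designs are refused with the collinear columns named.
Variables are z-scored after residualization so the path coefficients fitted
to their correlation matrix are directly standardized; fitting raw
covariances is available through `sample_moments(standardize = FALSE)`.

## 4. Numerical choices and degenerate inputs

* Positive-definiteness of $S$ is checked by Cholesky; non-PD input is an
  error, as is $n \le p$.
* A saturated model (df = 0) reports $F_{ML} = 0$, $T_{SB} = 0$, scaling
  $c = 1$ with a warning, CFI = 1, RMSEA = 0, SRMR = 0.
* Spin assignments break nearest-centroid ties at the lowest region index;
  rotations are QR-orthonormalized Gaussian matrices with the sign and
  determinant corrections that make them Haar-uniform on SO(3).
* Chains containing a zero coefficient report estimate 0 and z = 0; a zero
  delta-method SE likewise yields z = 0 rather than NaN.
* Regions with fewer than 10 complete cases (regressions) or 100
  (region-wise path models), or with zero variance, are reported missing.
* The scaled-difference guard: if $c_d \le 0$ the unscaled difference is
  used and a warning logged, never a negative statistic.

## 5. Problem sizes in the test suite

The suite regenerates everything programmatically. Cohort-scale checks run
at the study sizes (10 seeds at n = 21,738; 10 at n = 116,887); consistency
checks use single cohorts of 50,000–100,000; the scaled-LR type-I
calibration uses 2,000 replicates at n = 2,000; spin-null calibration uses
250 fresh rotation batches of 150 spins on a 120-parcel lattice (p-values
are grid-valued, so uniformity is checked after a randomized PIT); the
regional designed-recovery experiments use 3–10 seeds at n = 20,000 with
reduced parcel counts. These sizes were chosen so each check has comfortable
power against the failure it targets while the full suite stays quick to
run.

## 6. Known limitations

* Only observed-variable recursive models with diagonal residual covariance
  are supported — no latent variables, ordinal endogenous variables,
  residual correlations, FIML for missing data, or Bayesian estimation.
* Fitting a correlation matrix as if it were a covariance matrix is the
  field's common shortcut for standardized coefficients; SEs of variance
  parameters should not be over-interpreted under that convention.
* The spin test conditions on parcel centroids; it does not implement
  vertex-level nulls or generative alternatives (variogram-matched or
  spectral nulls).
* Cross-sectional path models do not license causal claims; the package
  quantifies the agreement between a directed hypothesis and observed
  correlations, nothing stronger.
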