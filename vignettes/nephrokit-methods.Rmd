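---
title: "Methods and design notes for nephrokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for nephrokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephrokit)
```

This vignette is the package's own account of the models it implements, the
choices made where the underlying methodology left details open, and what
the synthetic-data tests do and do not establish.

## The one-tissue compartment model

Dynamic ¹¹C-acetate PET measures kidney oxidative metabolism. The tissue
tracer concentration obeys

$$\frac{dC_t}{dt} = K_1\,C_a(t) - k_2\,C_t(t), \qquad
C_{PET}(t) = (1-v_b)\,C_t(t) + v_b\,C_a(t),$$

with three parameters: the uptake rate constant $K_1$ (mL plasma/min/mL
tissue), the clearance rate constant $k_2$ (1/min; for acetate, the rate at
which the tracer leaves as labeled CO$_2$, hence a surrogate for TCA-cycle
flux), and the fractional blood volume $v_b$ (unitless, in $[0,1]$). Blood
flow is derived as $F = K_1/E$ with a single-pass extraction fraction
$E = 0.52$, the value appropriate for renal acetate.

**Assumptions.** All curves are decay-corrected to injection time (standard
reconstruction output; an uncorrected path is out of scope). The input
function is a piecewise-linear interpolation of its samples, zero before the
first sample, with the last value held beyond the last sample. Under this
contract the convolution $C_t(t) = K_1 \int_0^t e^{-k_2(t-s)} C_a(s)\,ds$
has a closed form per linear segment, and frame averages are computed by
exact integration (for $k_2 > 0$ via the ODE identity
$\int C_t = (K_1 \int C_a - \Delta C_t)/k_2$; for $k_2 = 0$ by exact
polynomial quadrature). `simulate_tac()` therefore has no time-step
discretization error — the test suite verifies it against an independent
RK4 oracle at $\Delta t = 0.001$ min.

**ROI fitting.** `fit_roi()` solves the weighted nonlinear least-squares
problem with default weights proportional to frame duration (a proxy for
count-statistics weighting when no calibration data are available; the
protocol's early frames are short and noisy, late frames long and stable).
Rather than a generic 3-parameter optimizer, the fit exploits the model's
structure: for fixed $k_2$ the model is linear in
$\alpha = (1-v_b)K_1 \ge 0$ and $\beta = v_b \in [0,1]$, so the profile
cost over $k_2$ is minimized by a coarse log-spaced grid scan followed by
golden-section refinement, with the two linear coefficients solved exactly
(including the active-constraint candidates) at every $k_2$. This variable
projection is numerically equivalent to the full bounded problem and
recovers noise-free parameters to better than $10^{-4}$ relative across the
physiological grid, which a general-purpose quasi-Newton run from a single
start cannot guarantee. Bounds default to $K_1 \in [0,5]$,
$k_2 \in [0,5]$, $v_b \in [0,1]$; an all-zero tissue curve returns
$K_1 = 0$ with an "unidentifiable k2" flag; a zero input function is a
degenerate-input error. Both a fitted-$v_b$ and a fixed-$v_b$ mode are
provided, since published voxel-wise implementations differ on this point.

**Linearized form.** Integrating the model equation gives the operational
linear regression used voxel-wise:
$C_{PET} = \theta_1 \int C_a + \theta_2 \int C_{PET} + \theta_3 C_a$ with
$\theta_3 = v_b$, $k_2 = -\theta_2$,
$K_1 = (\theta_1 + \theta_2\theta_3)/(1-\theta_3)$. Integrals use the
trapezoid rule on frame mid-times; on densely sampled noise-free data the
linearized and nonlinear fits agree to $10^{-2}$ relative, the
discretization bias of the trapezoid on the coarse clinical schedule being
the dominant difference.

**Voxel-wise spatially constrained ridge.** The literature names the
family — linear ridge regression with a spatial constraint — but not its
parameters, so the package states them explicitly and exposes them all:
pass 1 is the unpenalized linearized fit per voxel; pass 2 re-solves each
voxel with penalty $(\theta - \tilde\theta)^T \Lambda (\theta -
\tilde\theta)$, where $\tilde\theta$ is the pass-1 coefficient field
smoothed by a $3\times3\times3$ Gaussian kernel ($\sigma = 1$ voxel)
renormalized over in-mask neighbors (so region boundaries do not bleed into
background), and $\Lambda = \lambda\,\sigma^2_{loc} I$ scales with the
locally smoothed pass-1 residual variance — noisier neighborhoods are
shrunk harder. $\lambda$ defaults to 0.1; $\lambda = 0$ reproduces the
per-voxel ordinary least squares exactly (asserted in the tests). Voxels
whose first pass fails (singular design) are excluded and counted.

**Segmentation.** The semi-automatic iso-contour tool thresholds a
duration-weighted early-window average image (default 40 s–4.5 min) at a
fraction (default 0.5) of the robust maximum — the 99th percentile, so a
single hot voxel cannot shift the contour — and keeps the largest
6-connected component (or the one containing a seed point). The threshold
fraction is not stated in the source methodology; 0.5 is the conventional
iso-contour choice and manual masks can be supplied anywhere a mask is
accepted.

## MRI maps

R2* and ADC are estimated by log-linear least squares on the
monoexponential decays $S(TE) = S_0 e^{-R2^* TE}$ and
$S(b) = S_0 e^{-b\,ADC}$; the estimator is exact on noise-free data for any
two or more distinct abscissae. A weighted variant (weights $\propto$
signal$^2$, the first-order correction for log-transformed homoscedastic
noise) is available; the unweighted default matches what a standard toolbox
does and its Monte-Carlo bias at 1% noise is below 2%, which the tests
measure. Negative fitted rates are floored at zero with a diagnostic flag
(physical constraint). FSOC is the pre-minus-post-furosemide R2*
difference; perfusion maps (pCASL) are consumed as ready-made values — only
ROI summarization applies, and medullary R2* is conventionally summarized
as a geometric mean (`summarize_map`).

## Clearance and Gomez hemodynamics

Steady-infusion clearance uses the printed formula per timed urine
collection: flow = volume/time, clearance = urine concentration × flow /
mean of the bracketing plasma concentrations. Periods are averaged;
periods deviating >30% from the median are flagged (flag only — exclusion
is an analyst decision). PAH clearance is converted to RPF by an extraction
fraction, constant 0.85 by default with a pluggable GFR-dependent hook,
because the exact adjustment used in the source studies is cited but not
printed; the extraction actually used is recorded on the output.

The Gomez equations are transcribed with all constants surfaced:
$P_{Bow} = 10$ mmHg, $K_{FG} = 0.1012$ mL/s/mmHg (configurable — a
diabetes-specific value may be appropriate and whether the source used one
is unstated), and 1328 as the conversion to dyne·s·cm⁻⁵. Flows are
converted to mL/s inside $\Delta P_F$ and inside both resistance
expressions; the formula set is validated against an independent hand
transcription to $10^{-9}$ and by its internal identities
($FF \cdot RPF = GFR$, $RBF(1-Hct) = RPF$, $P_{GLO}$ monotone in GFR).
Physical preconditions ($0 < FF < 1$, $RBF > GFR$, $MAP > P_{GLO}$) are
errors naming the violated constraint rather than silently propagated
nonsense.

## Clamp and metabolomics preprocessing

The M-value is the mean glucose infusion rate over the steady-state window,
defined as the final 30 minutes of a stage unless a window is supplied (the
source does not state its window). Lean normalization rescales by
weight/lean mass. NEFA suppression is the percent fall from baseline and
may be negative; its covariate adjustment (baseline NEFA, body fat) is
delegated to `adjusted_means()`. The DXA muscle-mass calibration is
$a \cdot ALM + b$: only $b = -0.63$ is printed; $a$ defaults to 1.13 (the
external calibration family the value comes from) but is configuration and
is always echoed in the result. Metabolomics preprocessing imputes missing
values at 20% of the per-metabolite observed minimum (below-detection-limit
assumption), then averages duplicate tissue sections per participant.

## Statistical layer

Group tests are two-sided: Welch t by default (pooled by flag),
Mann-Whitney exact for group sizes ≤ 8 without ties and the tie-corrected
normal approximation otherwise, χ² or Fisher for categorical phenotypes.
Adjusted means are OLS least-squares means at covariate grand means with
CIs from the model error variance. Spearman's ρ uses average ranks, p by
the t approximation; the covariate-adjusted companion regression is
reported on either the rank or the raw scale — both are provided and
labeled because the source does not say which was used. The two-sample KS
test is asymptotic: $D$ is the exact ECDF supremum distance and p comes
from the Kolmogorov series at $\sqrt{n_{eff}}D$,
$n_{eff} = n_a n_b/(n_a+n_b)$. Square-root regression runs OLS on
$\sqrt{y}$ and reports the group effect on that scale, as right-skewed
tissue-metabolite outcomes are reported. Power for the two-sided two-sample
t test uses the noncentral t with $df = n_1+n_2-2$ — base R's
`power.t.test` handles only equal groups, and the design of interest is 28
vs 12. Multiple-testing correction defaults to off (raw p), matching a
primary-endpoint analysis with a stated 0.05 threshold;
Benjamini–Hochberg can be applied downstream.

## The synthetic world

Generators state the study's printed conditions as their defaults and take
explicit seeds (stochastic generation without a seed refuses to run):

- `gen_aif()`: gamma-variate bolus, peak 0.8 min at 50 kBq/mL — the real
  input is a measured aorta curve, so the family is a modeling choice; the
  scale matches a typical clinical acetate injection.
- `gen_dynamic_phantom()`: block phantom with cortex
  ($K_1 = 0.20$, $k_2 = 0.18$, $v_b = 0.10$), medulla
  ($K_1 = 0.10$, $k_2 = 0.15$, $v_b = 0.05$) at the study's parameter
  scale (healthy-control-like cortical clearance; a T1D-like phantom uses
  cortical $k_2 = 0.16$), aorta voxels carrying the frame-averaged blood
  curve, multiplicative Gaussian noise (CV default 10%).
- `gen_mri_signals()`: monoexponential decays with multiplicative noise
  (CV default 1%); paired pre/post-furosemide series with a stated FSOC.
- `gen_clearance_study()`: constant plasma levels with urine concentrations
  back-computed so the noise-free study returns the truth exactly; noise
  (CV 5%) on urine concentrations.
- `gen_cohort()`: two-group tables drawn at the printed summaries
  (M-value 7.8 ± 2.6 vs 14.3 ± 4.0 mg/kg/min; cortical $k_2$ 0.16 ± 0.02
  vs 0.18 ± 0.02 min⁻¹; medullary 0.15 ± 0.03 vs 0.18 ± 0.02; log-normal
  GBM width with medians 521.5 vs 446.7 nm, $\sigma_{log} = 0.25$ chosen to
  reproduce the printed interquartile spread), with a configurable
  M–$k_2$ correlation (default 0.42).
- `gen_pseudotime()`: bimodal Gaussian mixtures with a location shift
  between groups, emulating per-cell pseudotime densities.

**What a green test establishes — and does not.** Noise models are
Gaussian and voxel-independent; real PET noise is count-driven,
reconstruction-correlated, and the real input function carries metabolite
and dispersion structure the identity-default parent fraction does not.
Phantoms are geometric blocks without partial-volume mixing or motion.
Parameter recovery on this world validates the estimators' correctness and
calibration, not their robustness to scanner physics; cohort-level group
differences are validated in distribution, not per participant. The null
calibration of the KS p-value is checked at 1,000 cells per group because
the asymptotic series is only expected to be uniform in that regime; at a
few hundred cells the approximation is visibly conservative.

## Numerical choices and degenerate inputs

- Exact segment-wise convolution and frame integration (no ODE grid);
  $k_2 < 10^{-12}$ switches to the exact $k_2 = 0$ quadrature branch.
- Variable-projection NLS: $k_2$ grid of 48 log-spaced points then
  `optimize` at tolerance $10^{-12}$; linear subproblem solved with
  explicit active-set candidates, so bound solutions are exact, not
  clipped iterates. Estimates outside bounds (possible for the linearized
  estimator under noise) are clipped and flagged `"clipped"`.
- Ties in Spearman use average ranks; KS handles ties by evaluating the
  ECDF difference at run ends.
- Degenerate inputs error early with named constraints (zero plasma
  concentration, empty masks, constant curves, fully missing metabolite
  columns) rather than returning NaN.

## Known limitations

No NIfTI I/O is bundled — images enter as R arrays, curves as CSV; no
attenuation/scatter modeling, no 2-tissue models, no pCASL quantification,
no mixed models or survival analysis. The muscle-mass multiplier and the
GFR-dependent PAH extraction are deliberately configuration, not defaults
silently applied to reports.
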