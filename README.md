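# nephrokit

Quantitative kidney phenotyping for deep-phenotyping studies of type 1
diabetes (T1D) and health: dynamic ¹¹C-acetate PET kinetic modeling,
multiparametric kidney MRI map estimation, iohexol/PAH clearance with Gomez
intraglomerular hemodynamics, hyperinsulinemic-euglycemic clamp indices, the
accompanying cohort-level statistics, and seeded synthetic-data generators
so that every estimator can be validated by parameter recovery without any
patient data.

## Who this is for

Researchers analyzing multimodal kidney physiology studies: PET physicists
fitting tissue time-activity curves, MRI scientists deriving R2*/ADC/FSOC
maps, and clinical physiologists computing clearance-based hemodynamics and
insulin-sensitivity metrics — all of whom need the computations to be
reproducible and testable at desk scale.

## The models

**PET kinetics.** Tissue tracer concentration follows the one-tissue
(two-compartment) model

    dC_t/dt = K1 · C_a(t) − k2 · C_t(t)
    C_PET(t) = (1 − v_b) · C_t(t) + v_b · C_a(t)

where `C_a` is the metabolite-corrected, sample-calibrated arterial input,
`K1` (mL/min/mL) is tracer uptake, `k2` (1/min) is tracer clearance — with
¹¹C-acetate a surrogate for TCA-cycle oxidative metabolism — and `v_b` is
the blood volume fraction. Blood flow is derived as `F = K1 / E` with a
single-pass extraction fraction `E = 0.52`. The forward model is solved in
closed form against a piecewise-linear input and averaged exactly over the
frame schedule (default 12 × 10 s, 8 × 30 s, 2 × 2 min, 4 × 5 min). ROI
fitting (`fit_roi`) is weighted nonlinear least squares returning a classed
model object; voxel-wise fitting (`voxelwise_fit`) uses linear ridge
regression with a spatial constraint (smoothed-prior penalty).

**MRI maps.** `S(TE) = S0·e^(−R2*·TE)` for BOLD R2*,
`FSOC = R2*_pre − R2*_post` across a furosemide challenge, and
`S(b) = S0·e^(−b·ADC)` for diffusion, all log-linear least squares; plus
total kidney volume and ROI map summaries (arithmetic or geometric mean).

**Renal physiology.** Per-period clearance `U·V̇/P̄` for iohexol (GFR) and
PAH (RPF after extraction correction), then the Gomez equations:
FF = GFR/RPF, RBF = RPF/(1−Hct), ΔP_F = GFR/K_FG,
C_M = (TP/FF)·ln(1/(1−FF)), π_G = 5(C_M − 2), P_GLO = ΔP_F + P_Bow + π_G,
R_A = ((MAP − P_GLO)/RBF)·1328, R_E = (GFR/(K_FG(RBF − GFR)))·1328, and
RVR = MAP/RBF.

**Metabolic phenotypes and statistics.** Clamp M-value and NEFA
suppression, DXA muscle mass, metabolomics imputation (20% of per-column
minimum) and duplicate averaging, two-group tests, covariate-adjusted
least-squares means, Spearman correlation, the asymptotic two-sample
Kolmogorov-Smirnov test, single-cell QC filtering (500–5,000 genes, <50%
mitochondrial), square-root-transformed regression, and noncentral-t power.

## Worked example

```r
library(nephrokit)

# simulate a cortical curve at study-scale kinetics and fit it back
aif   <- gen_aif()                          # gamma-variate blood input
truth <- pk_parameters(K1 = 0.18, k2 = 0.18, vb = 0.10)
obs   <- simulate_tac(truth, aif)           # 26-frame, 30-min protocol
fit   <- fit_roi(obs, aif)
summary(fit)
#> One-tissue compartment model fit
#>
#> Coefficients:
#>   K1   k2   vb
#> 0.18 0.18 0.10
#>
#> Derived flow F = K1/0.52 = 0.3462 mL/min/mL tissue
#> Weighted RSS: 1.097e-17 on 26 frames; converged: TRUE

# Gomez hemodynamics at a healthy-range operating point
gomez_profile(gfr = 147, rpf = 600, map_pressure = 93,
              hct = 0.42, total_protein = 7.0)
#> Gomez intraglomerular hemodynamic profile
#>   GFR 147.0  RPF 600.0  RBF 1034.5 mL/min   FF 0.245
#>   dP_F 24.21  pi_G 30.15  P_GLO 64.36 mmHg (P_Bow 10.0)
#>   R_A 2206  R_E 2174 dyne.s.cm-5   RVR 0.0899 mmHg.min/mL

# power to detect an 88 nm GBM-width difference (SD 78 nm) at n = 28 vs 12
ttest_power(28, 12, delta = 88, sd = 78)
#> [1] 0.8899386
```

The fitted coefficients reproduce the simulation truth because the forward
model and the fit share no code path beyond the model definition; the Gomez
profile shows a physiological intraglomerular pressure of ~64 mmHg at a
healthy filtration fraction of 0.245; the power value confirms the study's
design target of >80% power.

## Acceptance script

`scripts/acceptance.R` re-runs the package end-to-end on seeded synthetic
inputs — phantom generation, ROI and voxel-wise kinetic fitting, MRI map
recovery, clearance/Gomez hemodynamics, cohort statistics and the power
calculation — and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
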