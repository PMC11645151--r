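#' Synthetic arterial input function (gamma-variate)
#'
#' The measured aorta curve of an acetate study is emulated by a
#' gamma-variate bolus A t^alpha exp(-t/beta), zero at t = 0, scaled so the
#' peak value equals `amplitude` at `peak_time` (beta = peak_time / alpha).
#' The curve is sampled every second for `duration` minutes. Generation is
#' deterministic; the `seed` argument is accepted for interface uniformity
#' with the other generators.
#'
#' @param peak_time Time of the bolus peak, minutes (> 0).
#' @param amplitude Peak activity, kBq/mL (>= 0).
#' @param alpha Gamma-variate shape (> 0).
#' @param duration Sampling duration, minutes.
#' @param seed Unused (deterministic); kept for a uniform generator API.
#' @return An [input_function()] sampled at 1-second resolution.
#' @export
gen_aif <- function(peak_time = 0.8, amplitude = 50, alpha = 2,
                    duration = 30, seed = NULL) {
  if (peak_time <= 0 || alpha <= 0 || duration <= 0)
    stop("peak_time, alpha and duration must be positive")
  if (amplitude < 0) stop("amplitude must be >= 0")
  tt <- seq(0, duration, by = 1 / 60)
  beta <- peak_time / alpha
  shape <- tt^alpha * exp(-tt / beta)
  peak <- peak_time^alpha * exp(-alpha)
  vals <- if (amplitude == 0) rep(0, length(tt)) else amplitude * shape / peak
  input_function(tt, vals)
}

phantom_geometry <- function(dims = c(12, 12, 3)) {
  labels <- array(0L, dims)
  nx <- dims[1L]
  half <- floor((nx - 1) / 2)
  labels[1:half, , ] <- 1L                       # cortex
  labels[(half + 1):(nx - 1), , ] <- 2L          # medulla
  labels[nx, , ] <- 3L                           # aorta
  label_mask(labels, c("1" = "cortex", "2" = "medulla", "3" = "aorta"))
}

#' Synthetic dynamic PET phantom with known kinetics
#'
#' Builds a labelled phantom whose cortex and medulla voxels follow the
#' one-tissue model with region-specific parameters (defaults at the
#' physiological scale of the acetate study: cortex K1 = 0.20, k2 = 0.18,
#' vb = 0.10; medulla K1 = 0.10, k2 = 0.15, vb = 0.05; healthy-control-like
#' cortical clearance; a T1D-like phantom would carry cortical k2 = 0.16),
#' aorta voxels carry the frame-averaged blood curve, and multiplicative
#' Gaussian noise with coefficient of variation `noise_cv` is applied
#' voxel-wise.
#'
#' @param geometry A [label_mask()] with regions named cortex / medulla /
#'   aorta (background = 0); default a block phantom of `dims`.
#' @param params Named list of [pk_parameters()] for cortex and medulla.
#' @param aif An [input_function()]; default [gen_aif()].
#' @param schedule A [frame_schedule()]; default [acetate_schedule()].
#' @param noise_cv Coefficient of variation of multiplicative noise (0 for
#'   noise-free).
#' @param seed Integer seed; required when `noise_cv > 0`.
#' @param dims Phantom dimensions when `geometry` is not supplied.
#' @return List with `image` ([dynamic_pet_image()]), `mask`
#'   ([label_mask()]), and `truth` (seed, per-region parameters, noise
#'   model).
#' @export
gen_dynamic_phantom <- function(geometry = NULL,
                                params = list(
                                  cortex = pk_parameters(0.20, 0.18, 0.10),
                                  medulla = pk_parameters(0.10, 0.15, 0.05)),
                                aif = gen_aif(),
                                schedule = acetate_schedule(),
                                noise_cv = 0.10, seed = NULL,
                                dims = c(12, 12, 3)) {
  mask <- geometry %||% phantom_geometry(dims)
  region_of <- function(lab) mask$legend[[as.character(lab)]]
  labs <- setdiff(sort(unique(as.integer(mask$labels))), 0L)
  for (lab in labs) {
    nm <- region_of(lab)
    if (!nm %in% c(names(params), "aorta", "background"))
      stop("unknown region label: ", nm)
  }
  if (noise_cv > 0) seed <- require_seed(seed)
  nf <- n_frames(schedule)
  d <- dim(mask$labels)
  vox <- array(0, c(d, nf))
  pre <- otc_precompute(aif, schedule)
  frame_curves <- list()
  for (lab in labs) {
    nm <- region_of(lab)
    curve <- if (nm == "aorta") pre$Abar
             else simulate_tac(params[[nm]], aif, schedule)$activity
    frame_curves[[nm]] <- curve
    idx <- which(mask$labels == lab)
    nv <- prod(d)
    for (f in seq_len(nf)) vox[idx + (f - 1L) * nv] <- curve[f]
  }
  if (noise_cv > 0) {
    vox <- with_seed(seed, {
      vox * (1 + noise_cv * array(stats::rnorm(length(vox)), dim(vox)))
    })
  }
  truth <- list(seed = seed, parameters = params,
                noise = sprintf("multiplicative Gaussian, CV = %g", noise_cv),
                region_curves = frame_curves)
  list(image = dynamic_pet_image(vox, schedule), mask = mask, truth = truth)
}

#' Synthetic multi-echo and multi-b MRI signals with known truth
#'
#' Monoexponential mGRE decays before and after a simulated furosemide
#' challenge (post-furosemide R2* = pre - fsoc) and a monoexponential DWI
#' decay, each with multiplicative Gaussian noise.
#'
#' @param r2star_pre True pre-furosemide R2*, 1/s.
#' @param fsoc True furosemide-suppressible R2* drop, 1/s.
#' @param adc True apparent diffusion coefficient, mm2/s.
#' @param s0 Baseline signal amplitude.
#' @param te_list Echo times, seconds.
#' @param b_list b-values, s/mm2.
#' @param noise_cv Noise coefficient of variation (0 = noise-free).
#' @param n_rep Number of replicate signal sets.
#' @param seed Integer seed; required when `noise_cv > 0`.
#' @return List with `echo_pre`, `echo_post` (each a list of `signals`
#'   matrices rep x TE with `echo_times`), `dwi` (`signals` rep x b,
#'   `b_values`), and `truth`.
#' @export
gen_mri_signals <- function(r2star_pre = 30, fsoc = 3, adc = 1.5e-3,
                            s0 = 100,
                            te_list = c(4, 8, 12, 16, 24, 32) / 1000,
                            b_list = c(200, 300, 500, 700, 1000),
                            noise_cv = 0.01, n_rep = 1, seed = NULL) {
  if (r2star_pre <= 0 || adc <= 0 || s0 <= 0)
    stop("truth parameters must be positive")
  if (noise_cv > 0) seed <- require_seed(seed)
  clean_pre <- s0 * exp(-r2star_pre * te_list)
  clean_post <- s0 * exp(-(r2star_pre - fsoc) * te_list)
  clean_dwi <- s0 * exp(-adc * b_list)
  noisy <- function(clean, n) {
    m <- matrix(rep(clean, each = n), nrow = n)
    if (noise_cv > 0)
      m <- m * (1 + noise_cv * matrix(stats::rnorm(length(m)), nrow = n))
    m
  }
  out <- with_seed(if (noise_cv > 0) seed else NULL, {
    list(echo_pre = list(echo_times = te_list,
                         signals = noisy(clean_pre, n_rep)),
         echo_post = list(echo_times = te_list,
                          signals = noisy(clean_post, n_rep)),
         dwi = list(b_values = b_list, signals = noisy(clean_dwi, n_rep)))
  })
  out$truth <- list(seed = seed, R2star_pre = r2star_pre,
                    R2star_post = r2star_pre - fsoc, FSOC = fsoc,
                    ADC = adc, S0 = s0,
                    noise = sprintf("multiplicative Gaussian, CV = %g",
                                    noise_cv))
  out
}

#' Synthetic steady-infusion clearance study
#'
#' Constructs timed urine collection periods under constant plasma marker
#' levels, with urine concentrations back-computed so that the noise-free
#' periods return the true GFR (iohexol) and true RPF x e_PAH (PAH) exactly;
#' multiplicative noise is applied to the urine concentrations.
#'
#' @param true_gfr True GFR, mL/min.
#' @param true_rpf True renal plasma flow, mL/min.
#' @param n_periods Number of collection periods.
#' @param noise_cv Urine-concentration noise CV (0 = noise-free).
#' @param pah_extraction PAH extraction fraction used in construction.
#' @param plasma_iohexol,plasma_pah Steady plasma levels, ug/mL.
#' @param urine_flow Urine flow, mL/min.
#' @param period_minutes Duration of each collection, minutes.
#' @param seed Integer seed; required when `noise_cv > 0`.
#' @return List with `iohexol` and `pah` (data frames of periods) and
#'   `truth`.
#' @export
gen_clearance_study <- function(true_gfr = 147, true_rpf = 600,
                                n_periods = 4, noise_cv = 0.05,
                                pah_extraction = 0.85,
                                plasma_iohexol = 60, plasma_pah = 12,
                                urine_flow = 10, period_minutes = 30,
                                seed = NULL) {
  if (true_gfr <= 0 || true_rpf <= 0) stop("true GFR and RPF must be > 0")
  if (noise_cv > 0) seed <- require_seed(seed)
  mk <- function(clearance, plasma) {
    conc <- clearance * plasma / urine_flow
    data.frame(urine_volume = rep(urine_flow * period_minutes, n_periods),
               duration = rep(period_minutes, n_periods),
               urine_conc = rep(conc, n_periods),
               plasma_start = rep(plasma, n_periods),
               plasma_end = rep(plasma, n_periods))
  }
  io <- mk(true_gfr, plasma_iohexol)
  pa <- mk(true_rpf * pah_extraction, plasma_pah)
  if (noise_cv > 0) {
    noise <- with_seed(seed, stats::rnorm(2L * n_periods))
    io$urine_conc <- io$urine_conc * (1 + noise_cv * noise[seq_len(n_periods)])
    pa$urine_conc <- pa$urine_conc * (1 + noise_cv * noise[-seq_len(n_periods)])
  }
  list(iohexol = io, pah = pa,
       truth = list(seed = seed, GFR = true_gfr, RPF = true_rpf,
                    pah_extraction = pah_extraction,
                    noise = sprintf("multiplicative Gaussian on urine conc, CV = %g",
                                    noise_cv)))
}

#' Synthetic two-group cohort table
#'
#' Draws a participant table with the study's printed group summaries as
#' generative truth: M-value 7.8 +- 2.6 (T1D) vs 14.3 +- 4.0 (HC) mg/kg/min,
#' cortical k2 0.16 +- 0.02 vs 0.18 +- 0.02 1/min, medullary k2 0.15 +- 0.03
#' vs 0.18 +- 0.02 1/min, and log-normal GBM width with medians 521.5 vs
#' 446.7 nm. M-value and cortical k2 are drawn jointly with a configurable
#' correlation (default 0.42).
#'
#' @param n_t1d,n_hc Group sizes (each >= 2).
#' @param effect_config Named list overriding any of the defaults
#'   (`m_mean`, `m_sd`, `k2c_mean`, `k2c_sd`, `k2m_mean`, `k2m_sd`, each a
#'   c(T1D, HC) pair; `gbm_median` c(T1D, HC); `gbm_sdlog`; `cor_m_k2`).
#' @param seed Integer seed (required).
#' @return List with `table` (data frame: id, group and phenotype columns),
#'   `units` (named character vector), and `truth`.
#' @export
gen_cohort <- function(n_t1d = 28, n_hc = 12, effect_config = list(),
                       seed = NULL) {
  if (n_t1d < 2 || n_hc < 2) stop("need n >= 2 per group")
  seed <- require_seed(seed)
  cfg <- modifyList(list(
    m_mean = c(T1D = 7.8, HC = 14.3), m_sd = c(T1D = 2.6, HC = 4.0),
    k2c_mean = c(T1D = 0.16, HC = 0.18), k2c_sd = c(T1D = 0.02, HC = 0.02),
    k2m_mean = c(T1D = 0.15, HC = 0.18), k2m_sd = c(T1D = 0.03, HC = 0.02),
    gbm_median = c(T1D = 521.5, HC = 446.7), gbm_sdlog = 0.25,
    cor_m_k2 = 0.42), effect_config)
  rho <- cfg$cor_m_k2
  if (abs(rho) >= 1) stop("invalid covariance: |cor_m_k2| must be < 1")
  draw_group <- function(g, n) {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    data.frame(
      group = g,
      M_value = cfg$m_mean[[g]] + cfg$m_sd[[g]] * z1,
      k2_cortex = cfg$k2c_mean[[g]] + cfg$k2c_sd[[g]] * z2,
      k2_medulla = stats::rnorm(n, cfg$k2m_mean[[g]], cfg$k2m_sd[[g]]),
      gbm_width = stats::rlnorm(n, log(cfg$gbm_median[[g]]), cfg$gbm_sdlog))
  }
  tab <- with_seed(seed, rbind(draw_group("T1D", n_t1d),
                               draw_group("HC", n_hc)))
  tab <- cbind(id = sprintf("P%03d", seq_len(nrow(tab))), tab)
  units <- c(M_value = "mg/kg/min", k2_cortex = "1/min",
             k2_medulla = "1/min", gbm_width = "nm")
  list(table = tab, units = units,
       truth = list(seed = seed, config = cfg))
}

#' Synthetic pseudotime samples for two groups
#'
#' Emulates per-cell pseudotime densities compared between groups: each
#' group is a two-component Gaussian mixture on [0, 1]-scale pseudotime,
#' with a location shift applied to the second group.
#'
#' @param n_cells_per_group Cells per group (>= 1).
#' @param shift Location shift of group B relative to group A.
#' @param seed Integer seed (required).
#' @return List with samples `a`, `b` and `truth`.
#' @export
gen_pseudotime <- function(n_cells_per_group = 500, shift = 0, seed = NULL) {
  if (n_cells_per_group < 1) stop("need at least one cell per group")
  seed <- require_seed(seed)
  draw <- function(n, loc) {
    comp <- stats::rbinom(n, 1, 0.5)
    loc + ifelse(comp == 1, stats::rnorm(n, 0.3, 0.10),
                 stats::rnorm(n, 0.7, 0.15))
  }
  with_seed(seed, {
    a <- draw(n_cells_per_group, 0)
    b <- draw(n_cells_per_group, shift)
    list(a = a, b = b,
         truth = list(seed = seed, shift = shift,
                      mixture = "0.5 N(0.3, 0.1) + 0.5 N(0.7, 0.15)"))
  })
}
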