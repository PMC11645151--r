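test_that("gamma-variate input function: shape, peak, determinism", {
  aif <- gen_aif(peak_time = 0.8, amplitude = 50)
  expect_equal(max(aif$parent_activity), 50, tolerance = 1e-6)
  expect_equal(aif$parent_activity[1L], 0)
  # single interior maximum (grid-scan unimodality)
  v <- aif$parent_activity
  peaks <- sum(diff(sign(diff(v))) < 0)
  expect_equal(peaks, 1L)
  expect_equal(gen_aif(amplitude = 0)$parent_activity,
               rep(0, length(aif$sample_times)))
  expect_equal(gen_aif(seed = 1), gen_aif(seed = 2))  # deterministic
  expect_error(gen_aif(peak_time = -1), "positive")
})

test_that("noise-free phantom voxels equal the region model curves", {
  ph <- gen_dynamic_phantom(noise_cv = 0, dims = c(6, 4, 2))
  aif <- gen_aif()
  cortex_curve <- simulate_tac(pk_parameters(0.20, 0.18, 0.10), aif)$activity
  idx <- which(ph$mask$labels == 1L, arr.ind = TRUE)[1, ]
  expect_equal(ph$image$voxels[idx[1], idx[2], idx[3], ], cortex_curve)
  expect_equal(ph$truth$region_curves$cortex, cortex_curve)
  # aorta voxels carry the frame-averaged blood curve
  ai <- which(ph$mask$labels == 3L, arr.ind = TRUE)[1, ]
  pre <- simulate_tac(pk_parameters(0, 0, 1), aif)$activity
  expect_equal(ph$image$voxels[ai[1], ai[2], ai[3], ], pre)
})

test_that("phantom generation is seeded and reproducible", {
  p1 <- gen_dynamic_phantom(noise_cv = 0.1, seed = 5, dims = c(5, 4, 2))
  p2 <- gen_dynamic_phantom(noise_cv = 0.1, seed = 5, dims = c(5, 4, 2))
  expect_equal(p1$image$voxels, p2$image$voxels)
  p3 <- gen_dynamic_phantom(noise_cv = 0.1, seed = 6, dims = c(5, 4, 2))
  expect_false(identical(p1$image$voxels, p3$image$voxels))
  expect_error(gen_dynamic_phantom(noise_cv = 0.1), "seed")
})

test_that("noise-free MRI signals round-trip through the estimators", {
  sig <- gen_mri_signals(r2star_pre = 30, fsoc = 3, adc = 1.5e-3,
                         noise_cv = 0)
  pre <- fit_r2star(sig$echo_pre$echo_times, sig$echo_pre$signals[1, ])
  post <- fit_r2star(sig$echo_post$echo_times, sig$echo_post$signals[1, ])
  expect_equal(pre$R2star, 30, tolerance = 1e-9)
  expect_equal(compute_fsoc(pre$R2star, post$R2star), 3, tolerance = 1e-9)
  adc <- fit_adc(sig$dwi$b_values, sig$dwi$signals[1, ])
  expect_equal(adc$ADC, 1.5e-3, tolerance = 1e-12)
  s1 <- gen_mri_signals(noise_cv = 0.01, n_rep = 3, seed = 9)
  s2 <- gen_mri_signals(noise_cv = 0.01, n_rep = 3, seed = 9)
  expect_equal(s1$echo_pre$signals, s2$echo_pre$signals)
})

test_that("noise-free clearance study returns the exact truths", {
  st <- gen_clearance_study(true_gfr = 147, true_rpf = 600, noise_cv = 0)
  gfr <- aggregate_clearance(st$iohexol)$clearance
  expect_equal(gfr, 147)
  pah_cl <- aggregate_clearance(st$pah)$clearance
  expect_equal(as.numeric(rpf_from_pah(pah_cl)), 600)
  # noisy recovery: mean over seeds within 1% of truth
  ests <- vapply(1:200, function(s) {
    sim <- gen_clearance_study(147, 600, noise_cv = 0.05, seed = s)
    aggregate_clearance(sim$iohexol)$clearance
  }, numeric(1))
  expect_lt(abs(mean(ests) - 147) / 147, 0.01)
})

test_that("cohort generator carries the printed group summaries as truth", {
  coh <- gen_cohort(seed = 101)
  cfg <- coh$truth$config
  expect_equal(cfg$m_mean, c(T1D = 7.8, HC = 14.3))
  expect_equal(cfg$m_sd, c(T1D = 2.6, HC = 4.0))
  expect_equal(cfg$k2c_mean, c(T1D = 0.16, HC = 0.18))
  expect_equal(cfg$k2m_mean, c(T1D = 0.15, HC = 0.18))
  expect_equal(cfg$gbm_median, c(T1D = 521.5, HC = 446.7))
  expect_equal(nrow(coh$table), 40)
  expect_equal(coh$units[["M_value"]], "mg/kg/min")
  expect_equal(coh$units[["k2_cortex"]], "1/min")
  # large-n sample summaries approach the generative truth
  big <- gen_cohort(n_t1d = 2000, n_hc = 2000, seed = 77)
  t1d <- big$table[big$table$group == "T1D", ]
  expect_equal(mean(t1d$M_value), 7.8, tolerance = 0.05)
  expect_equal(mean(t1d$k2_cortex), 0.16, tolerance = 0.005)
  expect_equal(median(t1d$gbm_width), 521.5, tolerance = 0.05 * 521.5)
  # configured M-k2 correlation shows up in the sample Spearman
  rho <- spearman_cor(t1d$M_value, t1d$k2_cortex)$rho
  expect_lt(abs(rho - 0.4), 0.08)
  expect_error(gen_cohort(effect_config = list(cor_m_k2 = 1.5), seed = 1),
               "invalid covariance")
  expect_error(gen_cohort(seed = NULL), "seed")
})

test_that("zero-effect cohorts give nominal type-I error", {
  null_cfg <- list(m_mean = c(T1D = 10, HC = 10), m_sd = c(T1D = 3, HC = 3))
  pvals <- vapply(1:400, function(s) {
    coh <- gen_cohort(n_t1d = 15, n_hc = 15, effect_config = null_cfg,
                      seed = s)
    group_compare(coh$table$M_value, coh$table$group, "t")$p
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.035)
})

test_that("pseudotime generator: null calibration and separation", {
  ps <- gen_pseudotime(200, shift = 0, seed = 3)
  expect_equal(length(ps$a), 200)
  expect_equal(gen_pseudotime(50, 0.2, seed = 4),
               gen_pseudotime(50, 0.2, seed = 4))
  # large shift drives D toward 1
  far <- gen_pseudotime(300, shift = 50, seed = 5)
  expect_equal(ks_2sample(far$a, far$b)$D, 1)
  # under no shift the KS p-values are approximately uniform; cell counts
  # are in the asymptotic regime the p-value approximation presumes
  ps_p <- vapply(1:500, function(s) {
    g <- gen_pseudotime(1000, shift = 0, seed = s)
    ks_2sample(g$a, g$b)$p
  }, numeric(1))
  Dunif <- max(abs(sort(ps_p) - seq_along(ps_p) / length(ps_p)))
  expect_lt(Dunif, 0.05)
})
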