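test_that("frame schedule invariants are enforced", {
  sch <- acetate_schedule()
  expect_equal(length(sch), 26L)
  expect_equal(max(sch$end), 30)
  expect_equal(sch$dur[1:12], rep(10 / 60, 12))
  expect_error(frame_schedule(numeric(0), numeric(0)), "empty")
  expect_error(frame_schedule(c(0, 1), c(1.5, 2)), "overlap")
  expect_error(frame_schedule(c(0, 1), c(0.5, 1)), "end > start")
  expect_error(frame_schedule(-1, 1), "start must be >= 0")
})

test_that("simulate_tac trivial limits: no uptake, pure blood voxel", {
  aif <- gen_aif()
  sch <- acetate_schedule()
  zero <- simulate_tac(pk_parameters(0, 0.3, 0), aif, sch)
  expect_equal(zero$activity, rep(0, 26))

  blood <- simulate_tac(pk_parameters(0, 0, 1), aif, sch)
  # frame-averaged input function by dense trapezoid integration
  fa <- vapply(seq_len(26), function(i) {
    tt <- seq(sch$start[i], sch$end[i], length.out = 2001L)
    y <- eval_input(aif, tt)
    sum(diff(tt) * (y[-1] + y[-length(y)]) / 2) / sch$dur[i]
  }, numeric(1))
  expect_equal(blood$activity, fa, tolerance = 1e-6)
})

test_that("simulate_tac matches a fine-grid RK4 oracle on constant input", {
  sch <- acetate_schedule()
  aif <- input_function(seq(0, 30, by = 0.05), rep(1, 601))
  sim <- simulate_tac(pk_parameters(0.1, 0.2, 0), aif, sch)
  oracle <- rk4_frame_averages(0.1, 0.2, 0, function(t) rep(1, length(t)),
                               sch, dt = 0.001)
  expect_lt(max(abs(sim$activity - oracle) / oracle), 1e-5)
  # and the closed form 0.5 (1 - exp(-0.2 t)) integrated exactly per frame
  closed <- vapply(seq_len(26), function(i)
    stats::integrate(function(t) 0.5 * (1 - exp(-0.2 * t)),
                     sch$start[i], sch$end[i], rel.tol = 1e-12)$value /
      sch$dur[i], numeric(1))
  expect_equal(sim$activity, closed, tolerance = 1e-9)
})

test_that("simulate_tac is linear in K1 and monotone decreasing in k2", {
  aif <- gen_aif()
  sch <- acetate_schedule()
  s1 <- simulate_tac(pk_parameters(0.1, 0.2, 0), aif, sch)$activity
  s2 <- simulate_tac(pk_parameters(0.2, 0.2, 0), aif, sch)$activity
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  prev <- simulate_tac(pk_parameters(0.1, 0.05, 0), aif, sch)$activity
  for (k2 in c(0.1, 0.2, 0.5, 1)) {
    cur <- simulate_tac(pk_parameters(0.1, k2, 0), aif, sch)$activity
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("blood calibration scales by the sample ratio", {
  sch <- acetate_schedule()
  act <- seq(2, 52, by = 2)
  blood <- tac(sch, act, label = "aorta")
  img_at <- stats::approx(sch$mid, act, xout = 25.7)$y
  cal <- calibrate_input(blood, sample_time = 25.7,
                         sample_activity = 1.2 * img_at)
  expect_equal(cal$activity, act * 1.2)
  expect_equal(attr(cal, "calibration")$scale, 1.2)
  ident <- calibrate_input(blood, 25.7, img_at)
  expect_equal(ident$activity, act)
  zero <- tac(sch, rep(0, 26))
  expect_error(calibrate_input(zero, 25.7, 10), "cannot calibrate")
  expect_error(calibrate_input(blood, 45, 10), "outside the scan window")
})

test_that("metabolite correction multiplies by the parent fraction", {
  sch <- acetate_schedule()
  blood <- tac(sch, seq(26, 1), label = "aorta")
  expect_equal(metabolite_correct(blood, 1)$parent_activity, blood$activity)
  expect_equal(metabolite_correct(blood, 0.5)$parent_activity,
               blood$activity / 2)
  sig <- function(t) 1 / (1 + exp((t - 10) / 4))  # monotone-decreasing
  out <- metabolite_correct(blood, sig)
  expect_equal(out$parent_activity, blood$activity * sig(sch$mid))
  expect_error(metabolite_correct(blood, 1.2), "\\[0, 1\\]")
})

test_that("fit_roi recovers noise-free parameters and flags degeneracy", {
  aif <- gen_aif()
  truth <- pk_parameters(0.18, 0.18, 0.10)
  obs <- simulate_tac(truth, aif)
  fit <- fit_roi(obs, aif)
  expect_lt(max(abs(coef(fit) - c(0.18, 0.18, 0.10)) /
                  c(0.18, 0.18, 0.10)), 1e-4)
  expect_true(fit$converged)
  expect_s3_class(fit, "otc_fit")

  # all-zero tissue curve with live input: K1 = 0, k2 unidentifiable
  z <- tac(acetate_schedule(), rep(0, 26))
  fz <- fit_roi(z, aif)
  expect_equal(unname(coef(fz)["K1"]), 0)
  expect_true("unidentifiable k2" %in% fz$flags)

  # zero input and zero curve: degenerate
  aif0 <- input_function(c(0, 30), c(0, 0))
  expect_error(fit_roi(z, aif0), "degenerate input")
})

test_that("fit_roi with fixed vb honors the constraint", {
  aif <- gen_aif()
  obs <- simulate_tac(pk_parameters(0.2, 0.15, 0.08), aif)
  fit <- fit_roi(obs, aif, fix_vb = 0.08)
  expect_equal(unname(coef(fit)["vb"]), 0.08)
  expect_lt(abs(coef(fit)["K1"] - 0.2) / 0.2, 1e-4)
})

test_that("fit_roi noisy Monte-Carlo recovery: median K1 error <= 5%", {
  aif <- gen_aif()
  truth <- pk_parameters(0.18, 0.18, 0.10)
  clean <- simulate_tac(truth, aif)
  errs <- vapply(1:100, function(s) {
    noisy <- with_seed_test(s, clean$activity *
                              (1 + 0.05 * rnorm(26)))
    f <- fit_roi(tac(clean$schedule, pmax(noisy, 0)), aif)
    abs(coef(f)[["K1"]] - 0.18) / 0.18
  }, numeric(1))
  expect_lte(median(errs), 0.05)
})

test_that("otc_fit methods behave as a classed model fit", {
  aif <- gen_aif()
  obs <- simulate_tac(pk_parameters(0.18, 0.18, 0.10), aif)
  fit <- fit_roi(obs, aif)
  expect_named(coef(fit), c("K1", "k2", "vb"))
  expect_equal(fitted(fit) + residuals(fit), obs$activity)
  expect_output(print(fit), "One-tissue")
  sm <- summary(fit)
  expect_equal(sm$flow, coef(fit)[["K1"]] / 0.52)
  pr <- predict(fit)
  expect_s3_class(pr, "tac")
  expect_equal(pr$activity, fitted(fit), tolerance = 1e-10)
  sims <- simulate(fit, nsim = 2, seed = 7)
  sims2 <- simulate(fit, nsim = 2, seed = 7)
  expect_equal(sims, sims2)
})

test_that("linearized fit agrees with the nonlinear fit on dense data", {
  aif <- gen_aif()
  sch <- dense_schedule(30, dt = 2 / 60)
  truth <- pk_parameters(0.2, 0.18, 0.05)
  obs <- simulate_tac(truth, aif, sch)
  lf <- linearized_fit(obs, aif)
  nf <- fit_roi(obs, aif)
  for (p in c("K1", "k2", "vb"))
    expect_lt(abs(lf[[p]] - coef(nf)[[p]]) / max(coef(nf)[[p]], 1e-6), 1e-2)
  # vb recovered on noise-free data
  expect_lt(abs(lf$vb - 0.05) / 0.05, 1e-2)
})

test_that("linearized fit returns k2 = 0 for irreversible uptake", {
  aif <- gen_aif()
  sch <- dense_schedule(30, dt = 2 / 60)
  obs <- simulate_tac(pk_parameters(0.2, 0, 0.05), aif, sch)
  lf <- linearized_fit(obs, aif)
  expect_lt(abs(lf$k2), 1e-6)
  # singular design: constant curves
  flat <- tac(acetate_schedule(), rep(3, 26))
  aifc <- input_function(c(0, 30), c(1, 1))
  expect_error(linearized_fit(flat, aifc), "singular design")
})

test_that("estimate_flow divides K1 by the extraction fraction", {
  expect_equal(estimate_flow(0.52), 1.0)
  expect_equal(estimate_flow(0), 0)
  p <- pk_parameters(0.26, 0.2, 0.1)
  expect_equal(estimate_flow(p), 0.5)
  expect_equal(p$F * p$extraction_fraction, p$K1)
  expect_error(estimate_flow(0.2, extraction_fraction = 0), "> 0")
})

test_that("average_image weights frames by window overlap", {
  sch <- frame_schedule(c(0, 1), c(1, 2))
  vox <- array(0, c(2, 2, 1, 2))
  vox[, , , 1] <- 2; vox[, , , 2] <- 4
  img <- dynamic_pet_image(vox, sch)
  expect_equal(average_image(img, c(0, 2))[1, 1, 1], 3)
  expect_equal(average_image(img, c(0, 1))[1, 1, 1], 2)
  # partial overlap vs a fine Riemann oracle
  win <- c(0.6, 1.7)
  got <- average_image(img, win)[1, 1, 1]
  tt <- seq(win[1] + 5e-5, win[2] - 5e-5, by = 1e-4)
  oracle <- mean(ifelse(tt < 1, 2, 4))
  expect_lt(abs(got - oracle), 1e-9)
  expect_error(average_image(img, c(5, 6)), "does not overlap")
})

test_that("iso-contour masking selects bright connected structure", {
  img <- array(0, c(10, 10, 4))
  img[3:6, 3:6, 2:3] <- 10           # bright block
  img[9, 9, 1] <- 10                 # small disconnected speck
  m <- iso_contour_mask(img, 0.5)
  expect_equal(sum(m$labels), 4 * 4 * 2)  # largest component only
  expect_true(all(m$labels[3:6, 3:6, 2:3] == 1L))
  uni <- array(5, c(3, 3, 3))
  expect_equal(sum(iso_contour_mask(uni, 0.5)$labels), 27)
  two <- array(1, c(4, 4, 1)); two[1:2, , 1] <- 10
  m2 <- iso_contour_mask(two, 0.999)
  expect_equal(sum(m2$labels), 8)
  expect_error(iso_contour_mask(img, 1.2), "threshold_fraction")
})

test_that("TAC and input-function CSV round-trip", {
  sch <- acetate_schedule()
  x <- tac(sch, seq_len(26) / 2, label = "cortex")
  f <- tempfile(fileext = ".csv")
  write_tac_csv(x, f)
  y <- read_tac_csv(f, label = "cortex")
  expect_equal(y$activity, x$activity)
  expect_equal(y$schedule$start, sch$start)
  aif <- gen_aif()
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_min = aif$sample_times,
                              activity_kBq_mL = aif$parent_activity),
                   f2, row.names = FALSE)
  expect_equal(read_input_csv(f2)$parent_activity, aif$parent_activity)
  unlink(c(f, f2))
})
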