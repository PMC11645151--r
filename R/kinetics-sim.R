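#' One-tissue compartment model parameters
#'
#' Parameters of the one-tissue (two-compartment) pharmacokinetic model used
#' for dynamic acetate PET: `K1` is the uptake rate constant (mL plasma /
#' min / mL tissue), `k2` the tissue clearance rate constant (1/min; with
#' 11C-acetate a surrogate for TCA-cycle CO2 production), and `vb` the
#' fractional blood volume contributing to the PET signal. Blood flow `F`
#' is derived from `K1` through a fixed single-pass extraction fraction
#' (default 0.52).
#'
#' @param K1 Uptake rate constant, >= 0 (mL/min/mL).
#' @param k2 Clearance rate constant, >= 0 (1/min).
#' @param vb Blood volume fraction in [0, 1].
#' @param extraction_fraction Single-pass extraction fraction in (0, 1].
#' @return An object of class `pk_parameters` with a derived element `F`.
#' @examples
#' pk_parameters(0.18, 0.18, 0.10)
#' @export
pk_parameters <- function(K1, k2, vb = 0,
                          extraction_fraction = 0.52) {
  if (!is.finite(K1) || K1 < 0) stop("K1 must be finite and >= 0")
  if (!is.finite(k2) || k2 < 0) stop("k2 must be finite and >= 0")
  if (!is.finite(vb) || vb < 0 || vb > 1) stop("vb must be in [0, 1]")
  if (!is.finite(extraction_fraction) || extraction_fraction <= 0 ||
      extraction_fraction > 1)
    stop("extraction_fraction must be in (0, 1]")
  structure(list(K1 = K1, k2 = k2, vb = vb,
                 extraction_fraction = extraction_fraction,
                 F = K1 / extraction_fraction),
            class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf(
    "One-tissue model: K1 = %.4g mL/min/mL, k2 = %.4g 1/min, vb = %.4g\n",
    x$K1, x$k2, x$vb))
  cat(sprintf("Derived flow F = K1/%.3g = %.4g mL/min/mL\n",
              x$extraction_fraction, x$F))
  invisible(x)
}

#' Estimate blood flow from K1
#'
#' Converts the uptake rate constant to blood flow through a single-pass
#' extraction fraction: F = K1 / E.
#'
#' @param params A [pk_parameters()] object, or a numeric K1 value.
#' @param extraction_fraction Used when `params` is numeric; in (0, 1].
#' @return Flow in mL/min/mL tissue.
#' @export
estimate_flow <- function(params, extraction_fraction = 0.52) {
  if (inherits(params, "pk_parameters")) {
    K1 <- params$K1
    extraction_fraction <- params$extraction_fraction
  } else {
    K1 <- as.numeric(params)
  }
  if (!is.finite(extraction_fraction) || extraction_fraction <= 0)
    stop("extraction_fraction must be > 0")
  K1 / extraction_fraction
}

# Precompute the breakpoint geometry shared by every k2 evaluation against a
# fixed (input function, schedule) pair. Breakpoints are the union of input
# sample times and frame boundaries; within each interval the input is
# linear (identically zero before the first sample), so the convolution with
# exp(-k2 t) and all frame integrals are closed-form.
otc_precompute <- function(input_fn, schedule) {
  stopifnot(inherits(input_fn, "input_fn"),
            inherits(schedule, "frame_schedule"))
  t0 <- input_fn$sample_times[1L]
  tmax <- schedule$end[n_frames(schedule)]
  bp <- sort(unique(c(0, schedule$start, schedule$end,
                      input_fn$sample_times[input_fn$sample_times < tmax],
                      tmax)))
  bp <- bp[bp <= tmax + 1e-12]
  nb <- length(bp)
  aL <- eval_input(input_fn, bp[-nb])
  aR <- eval_input(input_fn, bp[-1L])
  # intervals entirely before the first sample carry zero input; the value
  # interpolated AT the first sample must not leak into the interval ending
  # there (the input may jump at its first sample)
  pre0 <- bp[-1L] <= t0 + 1e-15
  aL[pre0] <- 0
  aR[pre0] <- 0
  h <- diff(bp)
  seg_int <- h * (aL + aR) / 2              # exact per-segment input integral
  cum_a <- c(0, cumsum(seg_int))            # cumulative input integral at bp
  fstart <- match_break(schedule$start, bp)
  fend <- match_break(schedule$end, bp)
  a_frame <- cum_a[fend] - cum_a[fstart]    # exact per-frame input integral
  list(bp = bp, aL = aL, aR = aR, h = h, cum_a = cum_a,
       fstart = fstart, fend = fend,
       Abar = a_frame / schedule$dur, a_frame = a_frame,
       dur = schedule$dur)
}

match_break <- function(times, bp) {
  idx <- findInterval(times + 1e-12, bp)
  if (any(abs(bp[idx] - times) > 1e-9))
    stop("internal error: frame boundary not a breakpoint")
  idx
}

# Frame-averaged unit-K1, vb = 0 tissue curve for clearance rate k2:
# C_t(t) = integral_0^t exp(-k2 (t-s)) C_a(s) ds, averaged exactly over each
# frame. Uses the ODE identity int C_t = (int C_a - dC_t) / k2 for k2 > 0
# and exact polynomial integration at k2 = 0.
otc_conv_frames <- function(pre, k2) {
  nb <- length(pre$bp)
  ct <- numeric(nb)
  h <- pre$h
  aL <- pre$aL
  aR <- pre$aR
  slope <- (aR - aL) / h
  if (k2 > 1e-12) {
    ek <- exp(-k2 * h)
    E1 <- (1 - ek) / k2
    E2 <- (1 - ek * (1 + k2 * h)) / k2^2
    inc <- (aL + slope * h) * E1 - slope * E2
    for (i in seq_len(nb - 1L)) ct[i + 1L] <- ek[i] * ct[i] + inc[i]
    int_ct <- (pre$a_frame - (ct[pre$fend] - ct[pre$fstart])) / k2
  } else {
    # k2 = 0: C_t(t) = cumulative input integral; frame integral of C_t is
    # int_t1^t2 C_t(t1) + int_t1^t2 (t2 - s) C_a(s) ds, the inner integral
    # done per segment by Simpson (exact: quadrand is quadratic)
    ct <- pre$cum_a
    nf <- length(pre$fstart)
    int_ct <- numeric(nf)
    bp <- pre$bp
    for (f in seq_len(nf)) {
      i0 <- pre$fstart[f]; i1 <- pre$fend[f]
      t2 <- bp[i1]
      acc <- ct[i0] * (t2 - bp[i0])
      for (i in i0:(i1 - 1L)) {
        u0 <- bp[i]; u1 <- bp[i + 1L]; hh <- u1 - u0
        am <- (aL[i] + aR[i]) / 2
        f0 <- (t2 - u0) * aL[i]
        fm <- (t2 - (u0 + u1) / 2) * am
        f1 <- (t2 - u1) * aR[i]
        acc <- acc + hh / 6 * (f0 + 4 * fm + f1)
      }
      int_ct[f] <- acc
    }
  }
  int_ct / pre$dur
}

#' Forward-simulate a one-tissue compartment time-activity curve
#'
#' Solves dC_t/dt = K1 C_a(t) - k2 C_t(t) against a piecewise-linear input
#' function, forms the PET signal C_PET(t) = (1 - vb) C_t(t) + vb C_a(t),
#' and returns the exact time-average of C_PET over each frame of the
#' schedule. The convolution is closed-form per linear input segment and
#' frame averages are exact integrals (no time-step discretization error).
#'
#' @param params A [pk_parameters()] object.
#' @param input_fn An [input_function()] (metabolite-corrected, calibrated).
#' @param schedule A [frame_schedule()]; defaults to [acetate_schedule()].
#' @param label Label for the returned curve.
#' @return A [tac()] with the frame-averaged model curve.
#' @examples
#' aif <- input_function(seq(0, 30, by = 0.1),
#'                       rep(1, 301))  # constant unit input
#' simulate_tac(pk_parameters(0.1, 0.2, 0), aif, acetate_schedule())
#' @export
simulate_tac <- function(params, input_fn, schedule = acetate_schedule(),
                         label = "model") {
  stopifnot(inherits(params, "pk_parameters"))
  pre <- otc_precompute(input_fn, schedule)
  conv <- otc_conv_frames(pre, params$k2)
  act <- (1 - params$vb) * params$K1 * conv + params$vb * pre$Abar
  tac(schedule, act, label = label)
}
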