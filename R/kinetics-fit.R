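#' Fit the one-tissue compartment model to an ROI time-activity curve
#'
#' Weighted nonlinear least squares for (K1, k2, vb) against a measured
#' frame-averaged tissue curve. The model is linear in (K1, vb) once k2 is
#' fixed, so the fit uses variable projection: the profile cost over k2 is
#' minimized by a bracketed 1-D search (coarse grid then golden-section
#' refinement), with the two linear coefficients solved exactly by
#' constrained weighted least squares at every candidate k2. This is
#' numerically equivalent to the full 3-parameter bounded least-squares
#' problem but far more robust than a generic 3-D optimizer.
#'
#' Default weights are proportional to frame duration, a standard proxy for
#' count-statistics weighting when no calibration data are available.
#'
#' @param tac Observed [tac()] (frame-averaged kBq/mL).
#' @param input_fn Calibrated, metabolite-corrected [input_function()].
#' @param init Optional [pk_parameters()] giving the k2 search center
#'   (default K1=0.1, k2=0.1, vb=0.05; only k2 matters to the profiled
#'   search).
#' @param bounds Named list with elements `K1`, `k2`, `vb`, each a length-2
#'   numeric range. Defaults K1 in [0,5], k2 in [0,5], vb in [0,1].
#' @param weights Frame weights; default proportional to frame duration.
#' @param fix_vb Optional numeric: fix the blood volume fraction at this
#'   value instead of estimating it.
#' @return An object of class `otc_fit`: elements `parameters`
#'   ([pk_parameters()]), `fitted`, `residuals`, `weights`, `rss` (weighted
#'   residual sum of squares), `converged`, `flags` (character vector of
#'   diagnostics such as "unidentifiable k2" or "clipped"), `tac`,
#'   `input_fn`.
#' @examples
#' aif <- gen_aif(seed = 1)
#' truth <- pk_parameters(0.18, 0.18, 0.10)
#' obs <- simulate_tac(truth, aif)
#' fit <- fit_roi(obs, aif)
#' coef(fit)
#' @export
fit_roi <- function(tac, input_fn, init = NULL, bounds = NULL,
                    weights = NULL, fix_vb = NULL) {
  stopifnot(inherits(tac, "tac"), inherits(input_fn, "input_fn"))
  sch <- tac$schedule
  if (n_frames(sch) < 4L) stop("need at least 4 frames to fit")
  y <- tac$activity
  if (is.null(weights)) weights <- sch$dur
  if (length(weights) != length(y) || any(weights <= 0))
    stop("weights must be positive, one per frame")
  b <- modifyList(list(K1 = c(0, 5), k2 = c(0, 5), vb = c(0, 1)),
                  as.list(bounds %||% list()))
  pre <- otc_precompute(input_fn, sch)
  if (all(pre$Abar == 0) && all(y == 0))
    stop("cannot fit: degenerate input (blood curve and tissue curve are zero)")
  if (all(pre$Abar == 0))
    stop("cannot fit: input function is identically zero over the schedule")

  flags <- character(0)
  if (all(y == 0)) {
    # no signal: K1 = 0 is exact, k2 has no information
    flags <- c(flags, "unidentifiable k2")
    p <- pk_parameters(0, 0, 0)
    fitted <- rep(0, length(y))
    out <- structure(list(parameters = p, fitted = fitted,
                          residuals = y - fitted, weights = weights,
                          rss = 0, converged = TRUE, flags = flags,
                          tac = tac, input_fn = input_fn),
                     class = "otc_fit")
    return(out)
  }

  solve_lin <- function(k2) otc_profile(pre, y, weights, k2, b$vb, fix_vb)
  # coarse grid over the k2 range, then golden-section refinement around the
  # best bracket; the profile cost of this model is smooth and in practice
  # unimodal over physiological k2
  grid <- sort(unique(c(b$k2[1L],
                        exp(seq(log(max(1e-4, b$k2[1L] + 1e-4)),
                                log(max(b$k2[2L], 1e-3)), length.out = 48)),
                        if (!is.null(init)) init$k2)))
  grid <- grid[grid >= b$k2[1L] & grid <= b$k2[2L]]
  costs <- vapply(grid, function(k) solve_lin(k)$rss, numeric(1))
  i <- which.min(costs)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (lo == hi) {
    k2_hat <- lo
  } else {
    opt <- stats::optimize(function(k) solve_lin(k)$rss, c(lo, hi),
                           tol = 1e-12)
    k2_hat <- if (opt$objective <= costs[i]) opt$minimum else grid[i]
  }
  sol <- solve_lin(k2_hat)
  vb_hat <- if (is.null(fix_vb)) sol$beta else fix_vb
  K1_hat <- if (vb_hat < 1) sol$alpha / (1 - vb_hat) else 0
  if (K1_hat > b$K1[2L] || K1_hat < b$K1[1L]) {
    K1_hat <- min(max(K1_hat, b$K1[1L]), b$K1[2L])
    flags <- c(flags, "clipped")
  }
  p <- pk_parameters(K1_hat, k2_hat, vb_hat)
  fitted <- (1 - vb_hat) * K1_hat * sol$H + vb_hat * pre$Abar
  structure(list(parameters = p, fitted = fitted, residuals = y - fitted,
                 weights = weights,
                 rss = sum(weights * (y - fitted)^2),
                 converged = TRUE, flags = flags,
                 tac = tac, input_fn = input_fn),
            class = "otc_fit")
}

# constrained weighted LS in (alpha, beta) for fixed k2, where the model is
# y = alpha * H(k2) + beta * Abar, alpha = (1-vb) K1 >= 0, beta = vb in
# vb_bounds. Solves the unconstrained 2x2 system, then checks the active
# constraint candidates.
otc_profile <- function(pre, y, w, k2, vb_bounds, fix_vb = NULL) {
  H <- otc_conv_frames(pre, k2)
  A <- pre$Abar
  cost <- function(alpha, beta) {
    r <- y - alpha * H - beta * A
    sum(w * r^2)
  }
  if (!is.null(fix_vb)) {
    y2 <- y - fix_vb * A
    Hw <- sum(w * H * H)
    alpha <- if (Hw > 0) max(0, sum(w * H * y2) / Hw) else 0
    return(list(alpha = alpha, beta = fix_vb, H = H,
                rss = cost(alpha, fix_vb)))
  }
  hh <- sum(w * H * H); ha <- sum(w * H * A); aa <- sum(w * A * A)
  hy <- sum(w * H * y); ay <- sum(w * A * y)
  det <- hh * aa - ha * ha
  cand <- list()
  if (det > 1e-300 * max(hh * aa, 1)) {
    alpha <- (hy * aa - ay * ha) / det
    beta <- (hh * ay - ha * hy) / det
    if (alpha >= 0 && beta >= vb_bounds[1L] && beta <= vb_bounds[2L])
      cand[[length(cand) + 1L]] <- c(alpha, beta)
  }
  # boundary candidates: alpha = 0; beta at each bound
  for (beta0 in vb_bounds) {
    a <- if (hh > 0) max(0, (hy - beta0 * ha) / hh) else 0
    cand[[length(cand) + 1L]] <- c(a, beta0)
  }
  bfree <- if (aa > 0) sum(w * A * y) / aa else 0
  bfree <- min(max(bfree, vb_bounds[1L]), vb_bounds[2L])
  cand[[length(cand) + 1L]] <- c(0, bfree)
  rss <- vapply(cand, function(p) cost(p[1L], p[2L]), numeric(1))
  best <- cand[[which.min(rss)]]
  list(alpha = best[1L], beta = best[2L], H = H, rss = min(rss))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
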