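#' Linearized one-tissue compartment fit
#'
#' Operational linear form of the one-tissue model used by the voxel-wise
#' estimator. Integrating the model equation gives
#' \deqn{C_{PET}(t) = \theta_1 \int_0^t C_a + \theta_2 \int_0^t C_{PET}
#'   + \theta_3 C_a(t)}
#' with \eqn{\theta_3 = v_b}, \eqn{k_2 = -\theta_2} and
#' \eqn{K_1 = (\theta_1 + \theta_2\theta_3)/(1-\theta_3)}. The three
#' regressors are evaluated at frame mid-times, with cumulative integrals by
#' the trapezoid rule, and the coefficients estimated by ordinary least
#' squares. Estimates falling outside the physical bounds are clipped and
#' flagged.
#'
#' @inheritParams fit_roi
#' @param fix_vb Optional numeric: fix the blood volume fraction instead of
#'   estimating it.
#' @return A [pk_parameters()] object with attributes `theta` (the raw OLS
#'   coefficients) and `flags` (character; contains "clipped" when any
#'   parameter was clipped to its bound).
#' @export
linearized_fit <- function(tac, input_fn, bounds = NULL, fix_vb = NULL) {
  stopifnot(inherits(tac, "tac"), inherits(input_fn, "input_fn"))
  sch <- tac$schedule
  if (n_frames(sch) < 4L) stop("need at least 4 frames to fit")
  reg <- linfit_regressors(input_fn, sch)
  sol <- linfit_solve(tac$activity, reg, bounds, fix_vb)
  p <- pk_parameters(sol$K1, sol$k2, sol$vb)
  attr(p, "theta") <- sol$theta
  attr(p, "flags") <- sol$flags
  p
}

# input-side regressors shared across voxels: cumulative trapezoid integral
# of C_a on the mid-time grid (leading segment from t = 0) and C_a itself
linfit_regressors <- function(input_fn, schedule) {
  mids <- schedule$mid
  ca <- eval_input(input_fn, mids)
  ca0 <- eval_input(input_fn, 0)
  list(mids = mids, ca = ca,
       int_ca = cumtrapz0(mids, ca, ca0))
}

# cumulative trapezoid with a leading segment from (0, y0) to the first
# abscissa
cumtrapz0 <- function(x, y, y0 = 0) {
  dx <- diff(c(0, x))
  ym <- (c(y0, y[-length(y)]) + y) / 2
  cumsum(dx * ym)
}

linfit_solve <- function(y, reg, bounds = NULL, fix_vb = NULL) {
  b <- modifyList(list(K1 = c(0, 5), k2 = c(0, 5), vb = c(0, 1)),
                  as.list(bounds %||% list()))
  if (!is.null(fix_vb)) {
    X2 <- cbind(reg$int_ca, cumtrapz0(reg$mids, y, 0))
    qrX <- qr(X2)
    if (qrX$rank < 2L)
      stop("singular design: the curves carry no kinetic information ",
           "(constant or collinear regressors)")
    th <- qr.coef(qrX, y - fix_vb * reg$ca)
    theta <- c(th, fix_vb)
    X <- cbind(X2, reg$ca)
  } else {
  X <- cbind(reg$int_ca, cumtrapz0(reg$mids, y, 0), reg$ca)
  qrX <- qr(X)
  if (qrX$rank < 3L)
    stop("singular design: the curves carry no kinetic information ",
         "(constant or collinear regressors)")
  theta <- qr.coef(qrX, y)
  }
  vb <- theta[3L]
  k2 <- -theta[2L]
  K1 <- if (vb < 1) (theta[1L] + theta[2L] * vb) / (1 - vb) else 0
  flags <- character(0)
  clip <- function(v, r) min(max(v, r[1L]), r[2L])
  if (K1 < b$K1[1L] || K1 > b$K1[2L] || k2 < b$k2[1L] || k2 > b$k2[2L] ||
      vb < b$vb[1L] || vb > b$vb[2L]) flags <- "clipped"
  list(K1 = clip(K1, b$K1), k2 = clip(k2, b$k2), vb = clip(vb, b$vb),
       theta = unname(theta), flags = flags,
       rss = sum((y - X %*% theta)^2))
}
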