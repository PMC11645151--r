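#' @export
print.otc_fit <- function(x, ...) {
  cat("One-tissue compartment model fit\n")
  cat(sprintf("  K1 = %.4g mL/min/mL   k2 = %.4g 1/min   vb = %.4g\n",
              x$parameters$K1, x$parameters$k2, x$parameters$vb))
  cat(sprintf("  weighted RSS = %.4g over %d frames%s\n", x$rss,
              length(x$fitted),
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' @export
coef.otc_fit <- function(object, ...) {
  c(K1 = object$parameters$K1, k2 = object$parameters$k2,
    vb = object$parameters$vb)
}

#' @export
residuals.otc_fit <- function(object, ...) object$residuals

#' @export
fitted.otc_fit <- function(object, ...) object$fitted

#' Summary of a one-tissue compartment fit
#'
#' @param object An `otc_fit`.
#' @param ... Unused.
#' @return A list with parameter estimates, derived flow, weighted RSS, and
#'   diagnostic flags, printed in a compact table.
#' @export
summary.otc_fit <- function(object, ...) {
  out <- list(coefficients = coef(object),
              flow = object$parameters$F,
              extraction_fraction = object$parameters$extraction_fraction,
              rss = object$rss,
              n_frames = length(object$fitted),
              converged = object$converged,
              flags = object$flags)
  class(out) <- "summary.otc_fit"
  out
}

#' @export
print.summary.otc_fit <- function(x, ...) {
  cat("One-tissue compartment model fit\n\nCoefficients:\n")
  print(round(x$coefficients, 6))
  cat(sprintf("\nDerived flow F = K1/%.3g = %.4g mL/min/mL tissue\n",
              x$extraction_fraction, x$flow))
  cat(sprintf("Weighted RSS: %.4g on %d frames; converged: %s\n",
              x$rss, x$n_frames, x$converged))
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Predict the model curve of a fitted one-tissue model
#'
#' @param object An `otc_fit`.
#' @param schedule Optional [frame_schedule()]; defaults to the schedule the
#'   model was fitted on.
#' @param ... Unused.
#' @return A [tac()] of frame-averaged model activity.
#' @export
predict.otc_fit <- function(object, schedule = NULL, ...) {
  sch <- schedule %||% object$tac$schedule
  simulate_tac(object$parameters, object$input_fn, sch, label = "fitted")
}

#' Simulate noisy replicate curves from a fitted one-tissue model
#'
#' @param object An `otc_fit`.
#' @param nsim Number of replicate curves.
#' @param seed Integer seed (required for reproducibility).
#' @param noise_cv Coefficient of variation of multiplicative Gaussian noise.
#' @param ... Unused.
#' @return A list of [tac()] objects of length `nsim`.
#' @export
simulate.otc_fit <- function(object, nsim = 1, seed = NULL,
                             noise_cv = 0.05, ...) {
  clean <- predict(object)
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      noisy <- clean$activity *
        (1 + noise_cv * stats::rnorm(length(clean$activity)))
      tac(clean$schedule, noisy, label = sprintf("sim%02d", i))
    })
  })
}

#' Plot a one-tissue compartment fit
#'
#' Observed frame activity (points at frame mid-times) with the fitted model
#' curve overlaid.
#'
#' @param x An `otc_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.otc_fit <- function(x, ...) {
  mids <- x$tac$schedule$mid
  graphics::plot(mids, x$tac$activity, xlab = "time (min)",
                 ylab = "activity (kBq/mL)",
                 main = "One-tissue compartment fit", ...)
  graphics::lines(mids, x$fitted, col = "firebrick", lwd = 2)
  graphics::legend("topright", legend = c("observed", "fitted"),
                   pch = c(1, NA), lty = c(NA, 1),
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
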