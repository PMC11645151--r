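#' Calibrate an image-derived blood curve against a venous sample
#'
#' The aorta-derived blood curve is rescaled so that its piecewise-linear
#' value at the venous sampling time matches the well-counter measurement
#' (typically drawn ~25.7 min post-injection in the acetate protocol).
#'
#' @param blood_tac A [tac()] from a blood-pool ROI (frame values taken at
#'   frame mid-times for interpolation).
#' @param sample_time Venous sample time, minutes post-injection.
#' @param sample_activity Measured venous activity, kBq/mL.
#' @return The input [tac()] scaled by
#'   `sample_activity / value at sample_time`; the scale is recorded in
#'   attribute `"calibration"`.
#' @export
calibrate_input <- function(blood_tac, sample_time, sample_activity) {
  stopifnot(inherits(blood_tac, "tac"))
  sch <- blood_tac$schedule
  if (sample_time < sch$start[1L] || sample_time > sch$end[n_frames(sch)])
    stop("sample time lies outside the scan window")
  img_val <- stats::approx(sch$mid, blood_tac$activity, xout = sample_time,
                           rule = 2)$y
  if (!is.finite(img_val) || img_val <= 0)
    stop("cannot calibrate: image-derived activity at the sample time is <= 0")
  scale <- sample_activity / img_val
  out <- tac(sch, blood_tac$activity * scale, label = blood_tac$label,
             decay_corrected = blood_tac$decay_corrected)
  attr(out, "calibration") <- list(sample_time = sample_time,
                                   sample_activity = sample_activity,
                                   image_activity = img_val,
                                   scale = scale)
  out
}

#' Metabolite-correct a blood curve into a parent input function
#'
#' Multiplies the whole-blood activity by the parent (unmetabolized tracer)
#' fraction, evaluated at frame mid-times, and stores the result as the
#' sample points of an input function. The parent-fraction model for
#' 11C-acetate is supplied by the user; the default is identity (no
#' correction).
#'
#' @param blood_tac A calibrated blood [tac()].
#' @param parent_fraction Either a function of time (minutes) returning the
#'   parent fraction in [0, 1], or a single number, or a vector with one
#'   value per frame. Default 1 (no metabolites).
#' @return An [input_function()] of parent activity at frame mid-times.
#' @export
metabolite_correct <- function(blood_tac, parent_fraction = 1) {
  stopifnot(inherits(blood_tac, "tac"))
  mids <- blood_tac$schedule$mid
  pf <- if (is.function(parent_fraction)) parent_fraction(mids)
        else rep_len(as.numeric(parent_fraction), length(mids))
  if (any(!is.finite(pf)) || any(pf < 0) || any(pf > 1))
    stop("parent fraction must lie in [0, 1]")
  input_function(mids, blood_tac$activity * pf)
}
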