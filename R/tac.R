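#' Time-activity curves and blood input functions
#'
#' A time-activity curve (TAC) holds the frame-resolved activity
#' concentration (kBq/mL) of a region or voxel of a dynamic PET scan. An
#' input function holds the metabolite-corrected, calibrated arterial blood
#' concentration driving tissue kinetics, as sample points with a
#' piecewise-linear interpolation contract (zero before the first sample,
#' last value held after the last sample).
#'
#' @param schedule A [frame_schedule()].
#' @param activity Numeric vector, one value per frame (kBq/mL).
#' @param label ROI name (default "roi").
#' @param decay_corrected Logical; curves are assumed decay-corrected to
#'   injection time (reconstruction-standard).
#' @return `tac()` returns an object of class `tac`; `input_function()`
#'   returns class `input_fn`.
#' @export
tac <- function(schedule, activity, label = "roi", decay_corrected = TRUE) {
  stopifnot(inherits(schedule, "frame_schedule"))
  activity <- as.numeric(activity)
  if (length(activity) != n_frames(schedule))
    stop("activity length must equal the number of frames")
  if (any(!is.finite(activity))) stop("activity must be finite")
  structure(list(schedule = schedule, activity = activity, label = label,
                 decay_corrected = isTRUE(decay_corrected)),
            class = "tac")
}

#' @rdname tac
#' @param sample_times Numeric vector of sample times (minutes), strictly
#'   increasing.
#' @param parent_activity Numeric vector of parent-tracer activity (kBq/mL),
#'   nonnegative.
#' @export
input_function <- function(sample_times, parent_activity) {
  sample_times <- as.numeric(sample_times)
  parent_activity <- as.numeric(parent_activity)
  if (length(sample_times) < 2L) stop("need at least 2 input samples")
  if (length(sample_times) != length(parent_activity))
    stop("times and activities must have equal length")
  if (any(diff(sample_times) <= 0))
    stop("sample times must be strictly increasing")
  if (any(parent_activity < 0)) stop("input activity must be nonnegative")
  if (any(!is.finite(parent_activity))) stop("input activity must be finite")
  structure(list(sample_times = sample_times,
                 parent_activity = parent_activity),
            class = "input_fn")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("TAC '%s': %d frames, peak %.3g kBq/mL\n",
              x$label, length(x$activity), max(x$activity)))
  invisible(x)
}

#' @export
print.input_fn <- function(x, ...) {
  cat(sprintf("Input function: %d samples over [%.3g, %.3g] min, peak %.3g kBq/mL\n",
              length(x$sample_times), x$sample_times[1L],
              x$sample_times[length(x$sample_times)],
              max(x$parent_activity)))
  invisible(x)
}

#' Evaluate an input function at arbitrary times
#'
#' Piecewise-linear between samples, zero before the first sample, constant
#' at the last value after the last sample.
#'
#' @param input_fn An [input_function()].
#' @param times Numeric vector of times (minutes).
#' @return Numeric vector of activities (kBq/mL).
#' @export
eval_input <- function(input_fn, times) {
  stopifnot(inherits(input_fn, "input_fn"))
  out <- stats::approx(input_fn$sample_times, input_fn$parent_activity,
                       xout = times, method = "linear", rule = 2)$y
  out[times < input_fn$sample_times[1L]] <- 0
  out
}

#' Read / write TAC and input-function CSV files
#'
#' TAC files have columns `frame_start_min`, `frame_end_min`,
#' `activity_kBq_mL`; input-function files have `time_min`,
#' `activity_kBq_mL`.
#'
#' @param path File path.
#' @param label ROI label to attach on read.
#' @return `read_tac_csv` returns a [tac()]; `read_input_csv` an
#'   [input_function()].
#' @export
read_tac_csv <- function(path, label = "roi") {
  d <- utils::read.csv(path)
  need <- c("frame_start_min", "frame_end_min", "activity_kBq_mL")
  if (!all(need %in% names(d)))
    stop("TAC CSV must have columns: ", paste(need, collapse = ", "))
  tac(frame_schedule(d$frame_start_min, d$frame_end_min),
      d$activity_kBq_mL, label = label)
}

#' @rdname read_tac_csv
#' @param x A [tac()] to write.
#' @export
write_tac_csv <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  utils::write.csv(
    data.frame(frame_start_min = x$schedule$start,
               frame_end_min = x$schedule$end,
               activity_kBq_mL = x$activity),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_tac_csv
#' @export
read_input_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_min", "activity_kBq_mL")
  if (!all(need %in% names(d)))
    stop("input CSV must have columns: ", paste(need, collapse = ", "))
  input_function(d$time_min, d$activity_kBq_mL)
}
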