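#' Frame schedule for a dynamic PET acquisition
#'
#' A frame schedule is the list of contiguous (or at least non-overlapping)
#' time intervals over which a dynamic PET scan is binned. Times are in
#' minutes post-injection.
#'
#' @param start_times Numeric vector of frame start times (minutes).
#' @param end_times Numeric vector of frame end times (minutes).
#' @return An object of class `frame_schedule` with elements `start`, `end`,
#'   `mid` (frame mid-times) and `dur` (frame durations), all in minutes.
#' @examples
#' sch <- frame_schedule(c(0, 0.5), c(0.5, 1))
#' acetate_schedule()  # the default 26-frame 30-minute protocol
#' @export
frame_schedule <- function(start_times, end_times) {
  start_times <- as.numeric(start_times)
  end_times <- as.numeric(end_times)
  if (length(start_times) == 0L) stop("empty frame schedule")
  if (length(start_times) != length(end_times))
    stop("start_times and end_times must have equal length")
  if (any(!is.finite(start_times)) || any(!is.finite(end_times)))
    stop("frame times must be finite")
  if (start_times[1L] < 0) stop("first frame start must be >= 0")
  if (any(end_times <= start_times))
    stop("every frame must have end > start")
  if (any(diff(start_times) <= 0))
    stop("frame start times must be strictly increasing")
  if (any(start_times[-1L] < end_times[-length(end_times)] - 1e-12))
    stop("frames must not overlap")
  structure(
    list(start = start_times, end = end_times,
         mid = (start_times + end_times) / 2,
         dur = end_times - start_times),
    class = "frame_schedule")
}

#' @describeIn frame_schedule The 30-minute acetate protocol: 12 x 10 s,
#'   8 x 30 s, 2 x 2 min, 4 x 5 min (26 frames).
#' @export
acetate_schedule <- function() {
  dur <- c(rep(10 / 60, 12), rep(30 / 60, 8), rep(2, 2), rep(5, 4))
  end <- cumsum(dur)
  frame_schedule(c(0, end[-length(end)]), end)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %.3g-%.3g min\n",
              length(x$start), x$start[1L], x$end[length(x$end)]))
  invisible(x)
}

#' @export
length.frame_schedule <- function(x) length(x$start)

n_frames <- function(schedule) length(schedule$start)
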