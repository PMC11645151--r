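#' Dynamic PET image and label mask containers
#'
#' A dynamic PET image is a 4D array (x, y, z, frame) of activity
#' concentrations (kBq/mL) with its frame schedule and voxel size; a label
#' mask is a 3D integer array on the same grid with a legend mapping label
#' values to region names (e.g. cortex, medulla, aorta; 0 = background).
#'
#' @param voxels 4D numeric array (x, y, z, frame).
#' @param schedule A [frame_schedule()]; the 4th dimension must match.
#' @param voxel_size Length-3 positive numeric, mm per axis.
#' @return `dynamic_pet_image()` returns class `dynamic_pet_image`;
#'   `label_mask()` returns class `label_mask`.
#' @export
dynamic_pet_image <- function(voxels, schedule, voxel_size = c(2, 2, 2)) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(dim(voxels)) != 4L)
    stop("voxels must be a 4D (x, y, z, frame) array")
  if (dim(voxels)[4L] != n_frames(schedule))
    stop("frame axis length must equal the number of frames")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  structure(list(voxels = voxels, schedule = schedule,
                 voxel_size = voxel_size),
            class = "dynamic_pet_image")
}

#' @rdname dynamic_pet_image
#' @param labels 3D integer array of region labels (0 = background).
#' @param legend Named character vector mapping label values (as names) to
#'   region names, e.g. `c("1" = "cortex", "2" = "medulla")`.
#' @export
label_mask <- function(labels, legend) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  present <- setdiff(unique(as.integer(labels)), 0L)
  if (!all(as.character(present) %in% names(legend)))
    stop("unknown region label(s): ",
         paste(setdiff(as.character(present), names(legend)), collapse = ", "))
  structure(list(labels = labels, legend = legend), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(as.integer(x$labels[x$labels != 0L]),
                      levels = names(x$legend)))
  cat("Label mask", paste(dim(x$labels), collapse = "x"), "\n")
  for (lv in names(x$legend))
    cat(sprintf("  %s (%s): %d voxels\n", x$legend[[lv]], lv,
                as.integer(tab[lv])))
  invisible(x)
}

#' Duration-weighted average PET image over a time window
#'
#' Averages the dynamic frames that overlap a time window, weighting each
#' frame by the duration of its overlap with the window (partial frames
#' contribute proportionally). The default window of 40 s to 4.5 min is the
#' early vascular-rich phase used to draw kidney iso-contours.
#'
#' @param image A [dynamic_pet_image()].
#' @param window Length-2 numeric, minutes.
#' @return 3D numeric array of time-averaged activity.
#' @export
average_image <- function(image, window = c(40 / 60, 4.5)) {
  stopifnot(inherits(image, "dynamic_pet_image"))
  sch <- image$schedule
  ov <- pmax(0, pmin(sch$end, window[2L]) - pmax(sch$start, window[1L]))
  if (sum(ov) <= 0) stop("window does not overlap the frame schedule")
  w <- ov / sum(ov)
  d <- dim(image$voxels)
  out <- array(0, d[1:3])
  nv <- prod(d[1:3])
  for (f in which(w > 0))
    out <- out + w[f] * array(image$voxels[seq_len(nv) + (f - 1) * nv], d[1:3])
  out
}

#' Semi-automatic iso-contour segmentation of an average PET image
#'
#' Thresholds the image at a fraction of its robust maximum (the 99th
#' percentile) and keeps the largest 6-connected component (or the component
#' containing `seed_point`). This mimics the semi-automatic iso-contour
#' kidney delineation of early-phase acetate images; manual masks may be
#' supplied anywhere a mask is accepted.
#'
#' @param avg_image 3D numeric array (e.g. from [average_image()]).
#' @param threshold_fraction Fraction of the robust maximum, in (0, 1).
#' @param seed_point Optional length-3 integer voxel coordinate; the
#'   component containing it is kept instead of the largest one.
#' @param label_name Region name for the resulting mask legend.
#' @return A [label_mask()] with label 1 for the selected region.
#' @export
iso_contour_mask <- function(avg_image, threshold_fraction = 0.5,
                             seed_point = NULL, label_name = "roi") {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  robust_max <- stats::quantile(avg_image, 0.99, names = FALSE)
  thr <- threshold_fraction * robust_max
  sel <- avg_image >= thr
  if (!any(sel))
    stop(sprintf(
      "iso-contour empty at threshold %.3g; try threshold_fraction below %.3g",
      thr, max(avg_image) / robust_max))
  comp <- connected_components(sel)
  keep <- if (!is.null(seed_point)) {
    lab <- comp[seed_point[1L], seed_point[2L], seed_point[3L]]
    if (lab == 0L) stop("seed_point is below threshold")
    lab
  } else {
    which.max(tabulate(comp[comp > 0L]))
  }
  out <- array(0L, dim(avg_image))
  out[comp == keep] <- 1L
  label_mask(out, stats::setNames(label_name, "1"))
}

# 6-connected component labelling of a logical 3D array (iterative flood
# fill; fixtures are small)
connected_components <- function(sel) {
  d <- dim(sel)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(sel)
  off <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
               c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      co <- arrayInd(v, d)
      for (k in 1:6) {
        nb <- co + off[k, ]
        if (any(nb < 1L) || any(nb > d)) next
        li <- nb[1L] + (nb[2L] - 1L) * d[1L] + (nb[3L] - 1L) * d[1L] * d[2L]
        if (sel[li] && lab[li] == 0L) {
          lab[li] <- nxt
          stack <- c(stack, li)
        }
      }
    }
  }
  lab
}
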