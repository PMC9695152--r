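# Thermogram stacks: ROI time series and thermal-contrast metrics.
#
# A stack is an ordered set of 2-D temperature frames (°C) from an infrared
# camera or from the phantom simulator; regions of interest select the
# nanoparticle-doped ("tumoral") and surrounding ("healthy") areas.

#' Construct a thermogram stack
#'
#' @param frames List of numeric matrices (°C), all with the same dimensions
#'   and finite entries.
#' @param timestamps Frame times in seconds, strictly increasing, same length
#'   as `frames`.
#' @param pixel_pitch_mm Physical pixel pitch in mm per pixel.
#' @param ambient_temp Optional ambient temperature in °C; when absent,
#'   readers fall back to a frame-based estimate.
#' @param laser_on_s,laser_off_s Laser phase annotations carried into
#'   extracted traces (`laser_off_s = NA` when the laser stays on).
#' @return Object of class `thermogram_stack`.
#' @export
thermogram_stack <- function(frames, timestamps, pixel_pitch_mm,
                             ambient_temp = NULL,
                             laser_on_s = 0, laser_off_s = NA) {
  if (!is.list(frames) || length(frames) < 1L) {
    stop_argument("`frames` must be a non-empty list of matrices")
  }
  dims <- dim(frames[[1]])
  ok <- vapply(frames, function(f) {
    is.matrix(f) && identical(dim(f), dims) && all(is.finite(f))
  }, logical(1))
  if (!all(ok)) stop_argument("all frames must be finite matrices of equal shape")
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) != length(frames) ||
      (length(timestamps) > 1L && any(diff(timestamps) <= 0))) {
    stop_argument("`timestamps` must be strictly increasing, one per frame")
  }
  if (!is_scalar_number(pixel_pitch_mm) || pixel_pitch_mm <= 0) {
    stop_argument("`pixel_pitch_mm` must be > 0")
  }
  structure(
    list(frames = frames, timestamps = timestamps,
         pixel_pitch_mm = pixel_pitch_mm, ambient_temp = ambient_temp,
         laser_on_s = laser_on_s, laser_off_s = laser_off_s),
    class = "thermogram_stack"
  )
}

#' @export
print.thermogram_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Thermogram stack: %d frames of %dx%d px (%.3g mm/px), t = %.5g..%.5g s\n",
              length(x$frames), d[1], d[2], x$pixel_pitch_mm,
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' Construct a region-of-interest mask
#'
#' @param mask Logical matrix matching the frame shape, with at least one
#'   `TRUE` pixel.
#' @param label Optional label.
#' @return Object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = "") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop_argument("`mask` must be a logical matrix")
  }
  if (!any(mask)) stop_argument("ROI mask must contain at least one TRUE pixel")
  structure(list(mask = mask, label = as.character(label)), class = "roi_mask")
}

#' Rectangular ROI helper
#'
#' @param nrow,ncol Frame dimensions.
#' @param rows,cols Integer ranges of rows/columns included in the ROI.
#' @param label Optional label.
#' @return A [roi_mask()].
#' @export
roi_rect <- function(nrow, ncol, rows, cols, label = "") {
  m <- matrix(FALSE, nrow, ncol)
  m[rows, cols] <- TRUE
  roi_mask(m, label)
}

as_mask_matrix <- function(roi) {
  if (inherits(roi, "roi_mask")) roi$mask
  else if (is.matrix(roi) && is.logical(roi)) roi
  else stop_argument("expected an `roi_mask` or a logical matrix")
}

#' Extract an ROI temperature time series
#'
#' Reduces each frame over the ROI pixels with `max` (hotspot convention,
#' the default, matching peak-temperature camera readouts) or `mean`.  The
#' ambient reference is taken from the stack metadata when present, otherwise
#' from the mean of the first frame outside the ROI (or the whole first
#' frame when the ROI covers everything).
#'
#' @param stack A [thermogram_stack()] with at least 2 frames.
#' @param roi A [roi_mask()] matching the frame shape.
#' @param reducer `"max"` (default) or `"mean"`.
#' @return A [thermal_trace()].
#' @export
roi_timeseries <- function(stack, roi, reducer = c("max", "mean")) {
  stopifnot(inherits(stack, "thermogram_stack"))
  reducer <- match.arg(reducer)
  mask <- as_mask_matrix(roi)
  if (!identical(dim(mask), dim(stack$frames[[1]]))) {
    stop_argument("ROI shape does not match frame shape")
  }
  if (!any(mask)) stop_argument("ROI mask is empty")
  fun <- if (reducer == "max") max else mean
  temps <- vapply(stack$frames, function(f) fun(f[mask]), numeric(1))
  ambient <- stack$ambient_temp
  if (is.null(ambient)) {
    outside <- stack$frames[[1]][!mask]
    ambient <- if (length(outside)) mean(outside) else mean(stack$frames[[1]])
  }
  thermal_trace(
    times = stack$timestamps, temps = temps, ambient_temp = ambient,
    laser_on_time = stack$laser_on_s, laser_off_time = stack$laser_off_s,
    metadata = list(reducer = reducer, pixel_pitch_mm = stack$pixel_pitch_mm)
  )
}

#' Thermal contrast map
#'
#' Elementwise difference between the final frame and a baseline frame,
#' i.e. the temperature rise image accumulated over the stack.
#'
#' @param stack A [thermogram_stack()].
#' @param baseline_index Index of the baseline frame (default 1).
#' @return Numeric matrix of temperature differences in °C.
#' @export
thermal_contrast_map <- function(stack, baseline_index = 1) {
  stopifnot(inherits(stack, "thermogram_stack"))
  n <- length(stack$frames)
  if (!is_scalar_number(baseline_index) ||
      baseline_index < 1 || baseline_index > n) {
    stop_argument(sprintf("`baseline_index` must be in 1..%d", n))
  }
  stack$frames[[n]] - stack$frames[[baseline_index]]
}

#' Heat-dissipation metrics of a contrast map
#'
#' Maximum temperature rise inside the tumoral (inclusion) region and inside
#' the surrounding healthy region; the two masks must be disjoint.
#'
#' @param contrast Contrast matrix from [thermal_contrast_map()].
#' @param tumor,healthy Disjoint [roi_mask()]s (or logical matrices).
#' @return Named list `dT_tumor`, `dT_healthy` in °C.
#' @export
dissipation_metrics <- function(contrast, tumor, healthy) {
  tm <- as_mask_matrix(tumor)
  hm <- as_mask_matrix(healthy)
  if (!identical(dim(tm), dim(contrast)) || !identical(dim(hm), dim(contrast))) {
    stop_argument("mask shapes must match the contrast map")
  }
  if (any(tm & hm)) stop_argument("tumor and healthy masks overlap")
  list(dT_tumor = max(contrast[tm]), dT_healthy = max(contrast[hm]))
}
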