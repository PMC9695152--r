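# MTT assay reduction: per-well reference-corrected optical densities to
# percent viability relative to an untreated, non-irradiated control.

#' Construct an MTT plate
#'
#' @param wells Data frame with columns `well` (id), `group` (label),
#'   `od570`, `od670` (optical densities at the measurement and reference
#'   wavelengths), and `irradiated` (logical).  Valid wells satisfy
#'   `od570 >= od670 >= 0`; every (group, irradiated) cell needs >= 3
#'   replicate wells.
#' @return Object of class `mtt_plate`.
#' @export
mtt_plate <- function(wells) {
  wells <- as.data.frame(wells)
  req <- c("well", "group", "od570", "od670", "irradiated")
  if (!all(req %in% names(wells))) {
    stop_argument(paste("plate must have columns:", paste(req, collapse = ", ")))
  }
  if (!is.logical(wells$irradiated)) {
    wells$irradiated <- as.logical(wells$irradiated)
  }
  if (any(!is.finite(wells$od570)) || any(!is.finite(wells$od670)) ||
      any(wells$od670 < 0) || any(wells$od570 < wells$od670)) {
    stop_argument("every well must satisfy od570 >= od670 >= 0")
  }
  counts <- table(wells$group, wells$irradiated)
  if (any(counts[counts > 0] < 3)) {
    stop_argument("each (group, irradiated) cell needs >= 3 replicate wells")
  }
  structure(list(wells = wells), class = "mtt_plate")
}

#' @export
print.mtt_plate <- function(x, ...) {
  cat(sprintf("MTT plate: %d wells, %d groups\n",
              nrow(x$wells), length(unique(x$wells$group))))
  invisible(x)
}

#' Percent viability relative to an untreated control
#'
#' Computes the per-well net optical density `od570 - od670`, averages
#' within each (group, irradiated) cell, and normalizes to the mean net OD
#' of the non-irradiated control group.  The replicate standard deviation of
#' each cell is propagated onto the same percent scale.
#'
#' @param plate An [mtt_plate()].
#' @param control_group Label of the untreated control group; the plate must
#'   contain non-irradiated wells of this group.
#' @return Data frame with columns `group`, `irradiated`,
#'   `viability_percent`, `sd_percent`, `n`.
#' @examples
#' wells <- data.frame(
#'   well = sprintf("A%d", 1:6),
#'   group = rep(c("untreated", "treated"), each = 3),
#'   od570 = c(0.65, 0.66, 0.64, 0.38, 0.40, 0.39),
#'   od670 = 0.05, irradiated = FALSE
#' )
#' compute_viability(mtt_plate(wells), "untreated")
#' @export
compute_viability <- function(plate, control_group) {
  stopifnot(inherits(plate, "mtt_plate"))
  w <- plate$wells
  w$net <- w$od570 - w$od670
  ctrl <- w$group == control_group & !w$irradiated
  if (!any(ctrl)) {
    stop_argument(sprintf(
      "control group '%s' has no non-irradiated wells", control_group
    ))
  }
  ctrl_mean <- mean(w$net[ctrl])
  if (ctrl_mean <= 0) {
    stop_argument("control mean net OD is not positive")
  }
  cells <- unique(w[, c("group", "irradiated")])
  cells <- cells[order(cells$group, cells$irradiated), ]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- w$group == cells$group[i] & w$irradiated == cells$irradiated[i]
    net <- w$net[sel]
    data.frame(
      group = cells$group[i],
      irradiated = cells$irradiated[i],
      viability_percent = 100 * mean(net) / ctrl_mean,
      sd_percent = 100 * stats::sd(net) / ctrl_mean,
      n = length(net)
    )
  }))
  rownames(out) <- NULL
  out
}
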