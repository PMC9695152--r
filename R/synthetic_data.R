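# Seeded generators for every pipeline input, each embedding its ground
# truth in the output metadata so estimators can be validated end to end.

#' Additive Gaussian noise specification
#'
#' @param sigma Standard deviation per sample or pixel (°C or OD), >= 0.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0, seed = NULL) {
  if (!is_scalar_number(sigma) || sigma < 0) stop_argument("`sigma` must be >= 0")
  structure(list(sigma = sigma, seed = seed), class = "noise_spec")
}

#' Generate a synthetic thermal trace
#'
#' Single heating/cooling cycle from the lumped-capacitance forward model
#' sampled at the camera cadence, plus seeded Gaussian noise.  With
#' `sigma = 0` the output is bitwise-identical to [simulate_cycles()].
#'
#' @param params A [lumped_params()] object (the ground truth; recorded in
#'   the trace metadata).
#' @param on_duration,off_duration Heating and cooling phase lengths in
#'   seconds (defaults 900/900, the 15-min protocol).
#' @param sample_interval Sampling interval in seconds (default 60, one
#'   frame per minute).
#' @param noise A [noise_spec()].
#' @return A [thermal_trace()] with `metadata$ground_truth = params`.
#' @examples
#' p <- lumped_params(0.196, 0.56, 0.8, 300)
#' tr <- generate_trace(p, noise = noise_spec(0.2, seed = 1))
#' @export
generate_trace <- function(params, on_duration = 900, off_duration = 900,
                           sample_interval = 60, noise = noise_spec()) {
  stopifnot(inherits(params, "lumped_params"), inherits(noise, "noise_spec"))
  if (!is_scalar_number(sample_interval) || sample_interval <= 0) {
    stop_argument("`sample_interval` must be > 0")
  }
  trace <- simulate_cycles(params, on_duration, off_duration,
                           n_cycles = 1, dt = sample_interval)
  if (noise$sigma > 0) {
    trace$temps <- trace$temps + with_seed(
      noise$seed, stats::rnorm(length(trace$temps), sd = noise$sigma)
    )
  }
  trace$metadata$ground_truth <- params
  trace$metadata$noise <- noise
  trace
}

#' Generate a synthetic extinction spectrum
#'
#' Sum of Lorentzian line shapes (plasmon bands are homogeneously broadened)
#' on a regular wavelength grid, plus seeded Gaussian noise.
#'
#' @param modes Data frame (or list of lists) with columns/fields
#'   `center_nm`, `width_nm` (FWHM) and `height_od`; at least one mode, all
#'   centers inside the grid.
#' @param from,to,step Wavelength grid in nm (defaults 400-1100 nm, 1 nm).
#' @param noise A [noise_spec()] (sigma in OD).
#' @param label Sample label.
#' @return A [spectrum_record()]; ground truth is attached as
#'   `attr(, "modes")`.
#' @examples
#' sp <- generate_spectrum(data.frame(center_nm = c(534, 780),
#'                                    width_nm = c(60, 90),
#'                                    height_od = c(0.8, 0.56)))
#' find_lspr_peaks(sp)
#' @export
generate_spectrum <- function(modes, from = 400, to = 1100, step = 1,
                              noise = noise_spec(), label = "") {
  if (is.list(modes) && !is.data.frame(modes)) {
    modes <- do.call(rbind, lapply(modes, as.data.frame))
  }
  modes <- as.data.frame(modes)
  if (nrow(modes) < 1L) stop_argument("need at least one spectral mode")
  req <- c("center_nm", "width_nm", "height_od")
  if (!all(req %in% names(modes))) {
    stop_argument(paste("modes need fields:", paste(req, collapse = ", ")))
  }
  if (any(modes$center_nm < from) || any(modes$center_nm > to)) {
    stop_argument("all mode centers must lie inside the wavelength grid")
  }
  wl <- seq(from, to, by = step)
  od <- rep(0, length(wl))
  for (i in seq_len(nrow(modes))) {
    gamma <- modes$width_nm[i] / 2  # half width at half maximum
    od <- od + modes$height_od[i] * gamma^2 /
      ((wl - modes$center_nm[i])^2 + gamma^2)
  }
  if (noise$sigma > 0) {
    od <- od + with_seed(noise$seed,
                         stats::rnorm(length(od), sd = noise$sigma))
  }
  out <- spectrum_record(wl, od, label = label)
  attr(out, "modes") <- modes
  out
}

#' Generate a synthetic MTT plate
#'
#' Draws per-well net optical densities as
#' `control_od * effect * (1 + N(0, cv))` with a fixed small reference-band
#' OD, for a set of treatment groups with known true viability fractions.
#'
#' @param group_effects Either a named numeric vector of true viability
#'   fractions (wells generated as non-irradiated), or a data frame with
#'   columns `group`, `irradiated`, `effect`.  Must contain a non-irradiated
#'   control entry with effect 1.0; all effects >= 0.
#' @param control Label of the control group (default `"untreated"`).
#' @param replicates Wells per (group, irradiated) cell (default 3).
#' @param control_od Mean net OD of the control (default 0.6).
#' @param noise_cv Coefficient of variation of the well noise (default 0).
#' @param od670 Reference-wavelength OD added to every well (default 0.05).
#' @param seed RNG seed.
#' @return An [mtt_plate()]; ground truth attached as `attr(, "effects")`.
#' @examples
#' plate <- generate_mtt_plate(c(untreated = 1, AuNTs780 = 0.55))
#' compute_viability(plate, "untreated")
#' @export
generate_mtt_plate <- function(group_effects, control = "untreated",
                               replicates = 3, control_od = 0.6,
                               noise_cv = 0, od670 = 0.05, seed = NULL) {
  if (is.numeric(group_effects) && !is.null(names(group_effects))) {
    group_effects <- data.frame(
      group = names(group_effects),
      irradiated = FALSE,
      effect = as.numeric(group_effects)
    )
  }
  group_effects <- as.data.frame(group_effects)
  if (!all(c("group", "irradiated", "effect") %in% names(group_effects))) {
    stop_argument("`group_effects` needs group, irradiated, effect")
  }
  if (any(group_effects$effect < 0)) stop_argument("effects must be >= 0")
  is_ctrl <- group_effects$group == control & !group_effects$irradiated
  if (!any(is_ctrl) || any(group_effects$effect[is_ctrl] != 1)) {
    stop_argument(sprintf(
      "`group_effects` must contain non-irradiated control '%s' with effect 1.0",
      control
    ))
  }
  if (replicates < 3) stop_argument("`replicates` must be >= 3")

  n_cells <- nrow(group_effects)
  noise <- with_seed(seed, stats::rnorm(n_cells * replicates, sd = noise_cv))
  rows <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    net <- control_od * group_effects$effect[i] *
      (1 + noise[((i - 1) * replicates + 1):(i * replicates)])
    data.frame(
      well = sprintf("%s%s_%d", group_effects$group[i],
                     if (group_effects$irradiated[i]) "_irr" else "", seq_len(replicates)),
      group = group_effects$group[i],
      od570 = pmax(net, 0) + od670,
      od670 = od670,
      irradiated = group_effects$irradiated[i]
    )
  }))
  out <- mtt_plate(rows)
  attr(out, "effects") <- group_effects
  out
}
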