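# Shared fixtures: the standard irradiation rig of the thermal experiments
# (196 mW laser, samples normalized to OD 0.56, 15-min phases at 1/min).

water_only <- function() list(heat_component("water", 1, 4.184))

std_params <- function(efficiency, tau = 300, laser_power = 0.196,
                       absorbance = 0.56, components = water_only(),
                       parasitic_power = 0, ambient_temp = 25) {
  lumped_params(
    laser_power = laser_power, absorbance = absorbance,
    efficiency = efficiency, time_constant = tau,
    parasitic_power = parasitic_power, components = components,
    ambient_temp = ambient_temp
  )
}

# Euclidean distance (in cells) from each cell to the nearest TRUE cell.
distance_to_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  d <- matrix(Inf, nrow(mask), ncol(mask))
  rr <- row(mask); cc <- col(mask)
  for (i in seq_len(nrow(idx))) {
    d <- pmin(d, sqrt((rr - idx[i, 1])^2 + (cc - idx[i, 2])^2))
  }
  d
}

# Uniform-material grid helper for simulator property tests.
uniform_grid <- function(n = 32, dx = 0.25e-3, material = "dermal", ...) {
  phantom_grid(matrix(material, n, n), dx = dx, ...)
}
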