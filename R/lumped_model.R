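# Lumped-capacitance forward model of a laser-heated colloidal sample.
#
# The sample (nanoparticle suspension + solvent + container) is treated as a
# single uniform-temperature body with total heat capacity sum(m_i * C_i)
# exchanging heat with the environment at a rate proportional to the
# temperature rise.  Under constant irradiation the rise above ambient follows
#
#   dT(t) = tau * [I * (1 - 10^(-A)) * eta + Q0] / sum(m_i C_i) * (1 - e^(-t/tau))
#
# where I is the incident laser power (W), A the optical density at the
# excitation wavelength, eta the photothermal conversion efficiency, Q0 the
# parasitic power absorbed by solvent and container (W), and tau the thermal
# time constant (s).  After the laser is switched off the rise relaxes as
# dT(t) = dT_off * e^(-t/tau) with the same tau.

#' Heat-capacity component of the lumped system
#'
#' One massive component of the irradiated sample (e.g. the aqueous solvent or
#' the polypropylene vial) contributing `mass * specific_heat` to the total
#' heat capacity.
#'
#' @param label Character name of the component.
#' @param mass Mass in grams; must be positive.
#' @param specific_heat Specific heat in J/(g °C); must be positive.
#' @return An object of class `heat_component`.
#' @examples
#' heat_component("water", 1, 4.184)
#' @export
heat_component <- function(label, mass, specific_heat) {
  if (!is_scalar_number(mass) || mass <= 0) {
    stop_argument("`mass` must be a positive number (grams)")
  }
  if (!is_scalar_number(specific_heat) || specific_heat <= 0) {
    stop_argument("`specific_heat` must be a positive number (J/(g °C))")
  }
  structure(
    list(label = as.character(label), mass = mass, specific_heat = specific_heat),
    class = "heat_component"
  )
}

#' Default component inventory
#'
#' 1.0 g of water (4.184 J/(g °C)) in a 1.0 g polypropylene tube
#' (1.9 J/(g °C)), a typical Eppendorf-scale irradiation target.
#'
#' @return List of [heat_component()] objects.
#' @export
default_components <- function() {
  list(
    heat_component("water", 1.0, 4.184),
    heat_component("polypropylene tube", 1.0, 1.9)
  )
}

#' Total heat capacity of a component inventory
#'
#' @param components List of [heat_component()] objects.
#' @return Sum of `mass * specific_heat` in J/°C.
#' @export
heat_capacity <- function(components) {
  if (length(components) == 0L) stop_argument("`components` must be non-empty")
  sum(vapply(components, function(cc) cc$mass * cc$specific_heat, numeric(1)))
}

#' Parameters of the lumped-capacitance heating model
#'
#' Collects every quantity entering the heating law and the energy-balance
#' efficiency estimator for one experiment.
#'
#' @param laser_power Incident laser power I in watts (>= 0).
#' @param absorbance Optical density A at the excitation wavelength (>= 0);
#'   the absorbed fraction of incident light is `1 - 10^(-absorbance)`.
#' @param efficiency Photothermal conversion efficiency eta in \[0, 1\].
#' @param time_constant Thermal time constant tau in seconds (> 0).
#' @param parasitic_power Power Q0 in watts absorbed by solvent and container
#'   rather than the nanoparticles (default 0).
#' @param components List of [heat_component()]; defaults to
#'   [default_components()].
#' @param ambient_temp Ambient temperature in °C (default 25).
#' @return An object of class `lumped_params`.
#' @examples
#' p <- lumped_params(laser_power = 0.196, absorbance = 0.56,
#'                    efficiency = 0.8, time_constant = 300)
#' steady_state_delta_t(p)
#' @export
lumped_params <- function(laser_power, absorbance, efficiency, time_constant,
                          parasitic_power = 0,
                          components = default_components(),
                          ambient_temp = 25) {
  if (!is_scalar_number(laser_power) || laser_power < 0) {
    stop_argument("`laser_power` must be >= 0 (watts)")
  }
  if (!is_scalar_number(absorbance) || absorbance < 0) {
    stop_argument("`absorbance` must be >= 0 (OD)")
  }
  if (!is_scalar_number(efficiency) || efficiency < 0 || efficiency > 1) {
    stop_argument("`efficiency` must lie in [0, 1]")
  }
  if (!is_scalar_number(time_constant) || time_constant <= 0) {
    stop_argument("`time_constant` must be > 0 (seconds)")
  }
  if (!is_scalar_number(parasitic_power) || parasitic_power < 0) {
    stop_argument("`parasitic_power` must be >= 0 (watts)")
  }
  if (length(components) == 0L) stop_argument("`components` must be non-empty")
  components <- lapply(components, function(cc) {
    if (inherits(cc, "heat_component")) cc
    else heat_component(cc$label, cc$mass, cc$specific_heat)
  })
  structure(
    list(
      laser_power = laser_power,
      absorbance = absorbance,
      efficiency = efficiency,
      parasitic_power = parasitic_power,
      components = components,
      time_constant = time_constant,
      ambient_temp = ambient_temp
    ),
    class = "lumped_params"
  )
}

#' @export
print.lumped_params <- function(x, ...) {
  cat("Lumped-capacitance system\n")
  cat(sprintf("  laser power      : %.4g W\n", x$laser_power))
  cat(sprintf("  absorbance       : %.3g OD (absorbed fraction %.3f)\n",
              x$absorbance, 1 - 10^(-x$absorbance)))
  cat(sprintf("  efficiency       : %.3f\n", x$efficiency))
  cat(sprintf("  parasitic power  : %.4g W\n", x$parasitic_power))
  cat(sprintf("  time constant    : %.4g s\n", x$time_constant))
  cat(sprintf("  heat capacity    : %.4g J/°C (%d components)\n",
              heat_capacity(x$components), length(x$components)))
  cat(sprintf("  ambient          : %.2f °C\n", x$ambient_temp))
  invisible(x)
}

# Total power converted to heat inside the lumped body, in watts.
absorbed_power <- function(params) {
  params$laser_power * (1 - 10^(-params$absorbance)) * params$efficiency +
    params$parasitic_power
}

#' Temperature rise under irradiation at time t
#'
#' Evaluates the lumped-capacitance heating law
#' `dT(t) = dT_ss * (1 - exp(-t / tau))` with steady state
#' `dT_ss = tau * (I (1 - 10^-A) eta + Q0) / sum(m_i C_i)`.
#'
#' @param params A [lumped_params()] object.
#' @param t Time(s) since the laser was switched on, in seconds (>= 0);
#'   vectorized.
#' @return Temperature rise(s) above ambient in °C.
#' @export
predict_delta_t <- function(params, t) {
  stopifnot(inherits(params, "lumped_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop_argument("`t` must be finite and >= 0 (seconds)")
  }
  steady_state_delta_t(params) * (1 - exp(-t / params$time_constant))
}

#' Steady-state temperature rise
#'
#' The limit of [predict_delta_t()] for long irradiation:
#' `tau * (I (1 - 10^-A) eta + Q0) / sum(m_i C_i)`.
#'
#' @param params A [lumped_params()] object.
#' @return Steady-state rise above ambient in °C.
#' @export
steady_state_delta_t <- function(params) {
  stopifnot(inherits(params, "lumped_params"))
  params$time_constant * absorbed_power(params) / heat_capacity(params$components)
}

#' Construct a thermal trace
#'
#' A timestamped temperature record of one irradiated sample, with its ambient
#' reference and laser-phase annotations.
#'
#' @param times Sample times in seconds, strictly increasing from 0.
#' @param temps Temperatures in °C, same length as `times`, all finite.
#' @param ambient_temp Ambient (environment) temperature in °C.
#' @param laser_on_time Time the laser was switched on (s), default 0.
#' @param laser_off_time Time the laser was switched off (s), or `NA` if the
#'   trace contains no cooling phase.
#' @param metadata Free-form named list (e.g. laser power, sample label,
#'   ground-truth generator parameters).
#' @return An object of class `thermal_trace`.
#' @export
thermal_trace <- function(times, temps, ambient_temp,
                          laser_on_time = 0, laser_off_time = NA,
                          metadata = list()) {
  times <- as.numeric(times)
  temps <- as.numeric(temps)
  if (length(times) != length(temps) || length(times) < 2L) {
    stop_argument("`times` and `temps` must have equal length >= 2")
  }
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop_argument("`times` must be finite and strictly increasing")
  }
  if (any(!is.finite(temps))) stop_argument("all `temps` must be finite")
  if (!is_scalar_number(ambient_temp)) stop_argument("`ambient_temp` must be a number")
  if (!is.na(laser_off_time) && laser_on_time > laser_off_time) {
    stop_argument("`laser_on_time` must be <= `laser_off_time`")
  }
  structure(
    list(
      times = times, temps = temps, ambient_temp = ambient_temp,
      laser_on_time = laser_on_time, laser_off_time = laser_off_time,
      metadata = metadata
    ),
    class = "thermal_trace"
  )
}

#' @export
print.thermal_trace <- function(x, ...) {
  cat(sprintf(
    "Thermal trace: %d samples over %.5g s, ambient %.2f °C\n",
    length(x$times), max(x$times) - min(x$times), x$ambient_temp
  ))
  cat(sprintf("  laser on at %.5g s, off at %s\n", x$laser_on_time,
              if (is.na(x$laser_off_time)) "<absent>"
              else sprintf("%.5g s", x$laser_off_time)))
  cat(sprintf("  temperature range %.2f .. %.2f °C\n",
              min(x$temps), max(x$temps)))
  invisible(x)
}

#' @export
as.data.frame.thermal_trace <- function(x, ...) {
  data.frame(time_s = x$times, temp_C = x$temps)
}

#' Simulate repeated laser on/off irradiation cycles
#'
#' Chains the closed-form heating and Newtonian-cooling solutions across
#' `n_cycles` cycles of `on_duration` seconds of irradiation followed by
#' `off_duration` seconds of relaxation.  Heating phases follow the lumped
#' law from the rise at phase start,
#' `dT(t) = dT_ss + (dT_start - dT_ss) exp(-t/tau)`; cooling phases follow
#' `dT(t) = dT_start * exp(-t/tau)` with the same tau.
#'
#' @param params A [lumped_params()] object.
#' @param on_duration,off_duration Phase lengths in seconds (> 0).
#' @param n_cycles Number of cycles (>= 1).
#' @param dt Sampling interval in seconds (> 0, < `on_duration`).
#' @return A [thermal_trace()]; `metadata$phases` is a data frame annotating
#'   each phase (cycle, phase, start_s, end_s), and the trace's
#'   `laser_on_time`/`laser_off_time` refer to the first cycle.
#' @examples
#' p <- lumped_params(0.196, 0.56, 0.8, 300)
#' tr <- simulate_cycles(p, 900, 900, n_cycles = 4, dt = 60)
#' @export
simulate_cycles <- function(params, on_duration, off_duration, n_cycles = 1,
                            dt = 60) {
  stopifnot(inherits(params, "lumped_params"))
  if (!is_scalar_number(on_duration) || on_duration <= 0 ||
      !is_scalar_number(off_duration) || off_duration <= 0) {
    stop_argument("`on_duration` and `off_duration` must be > 0")
  }
  if (!is_scalar_number(n_cycles) || n_cycles < 1) {
    stop_argument("`n_cycles` must be >= 1")
  }
  if (!is_scalar_number(dt) || dt <= 0 || dt >= on_duration) {
    stop_argument("`dt` must satisfy 0 < dt < on_duration")
  }
  n_cycles <- as.integer(n_cycles)
  tau <- params$time_constant
  ss <- steady_state_delta_t(params)
  period <- on_duration + off_duration

  # rise at the start of each heating phase, chained across cycles
  start_rise <- numeric(n_cycles)
  peak_rise <- numeric(n_cycles)
  d0 <- 0
  for (cyc in seq_len(n_cycles)) {
    start_rise[cyc] <- d0
    peak <- ss + (d0 - ss) * exp(-on_duration / tau)
    peak_rise[cyc] <- peak
    d0 <- peak * exp(-off_duration / tau)
  }

  times <- seq(0, n_cycles * period, by = dt)
  cyc_idx <- pmin(floor(times / period), n_cycles - 1L)
  t_in <- times - cyc_idx * period
  heating <- t_in <= on_duration
  rise <- numeric(length(times))
  rise[heating] <- ss + (start_rise[cyc_idx[heating] + 1L] - ss) *
    exp(-t_in[heating] / tau)
  rise[!heating] <- peak_rise[cyc_idx[!heating] + 1L] *
    exp(-(t_in[!heating] - on_duration) / tau)

  phases <- data.frame(
    cycle = rep(seq_len(n_cycles), each = 2L),
    phase = rep(c("heating", "cooling"), n_cycles),
    start_s = as.vector(rbind((seq_len(n_cycles) - 1L) * period,
                              (seq_len(n_cycles) - 1L) * period + on_duration)),
    end_s = as.vector(rbind((seq_len(n_cycles) - 1L) * period + on_duration,
                            seq_len(n_cycles) * period))
  )

  thermal_trace(
    times = times,
    temps = params$ambient_temp + rise,
    ambient_temp = params$ambient_temp,
    laser_on_time = 0,
    laser_off_time = on_duration,
    metadata = list(phases = phases, params = params,
                    cycle_peak_rise = peak_rise)
  )
}
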