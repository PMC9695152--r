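# Explicit finite-difference heat diffusion in a layered skin-mimicking
# phantom with a nanoparticle-doped inclusion.
#
# The phantom is modelled as a 2-D cross-section of unit depth:
#   dT/dt = div(k grad T) / (rho c) + S / (rho c)
# stepped forward-time / central-space in flux form (face conductivities as
# arithmetic means), which conserves energy exactly on insulated grids.  The
# laser enters only through an effective volumetric source S confined to the
# inclusion: a Gaussian lateral beam profile, normalized so the total
# deposited power equals power * absorbed_fraction * efficiency.

#' Construct a phantom grid
#'
#' Low-level constructor; most users call [build_phantom()].
#'
#' @param material Character matrix of cell labels (`"dermal"`,
#'   `"epidermal"`, `"inclusion"`); rows run from the irradiated surface
#'   downward.
#' @param dx Cell size in metres.
#' @param properties Named list mapping each material label to
#'   `list(k = <W/(m °C)>, rho_c = <J/(m^3 °C)>)`.
#' @param boundary `list(type = "insulated")` or
#'   `list(type = "convective", h = <W/(m^2 °C)>, T_ext = <°C>)` applied on
#'   all four edges.
#' @param initial_temp Initial uniform temperature in °C, or a matrix of
#'   per-cell temperatures.
#' @return Object of class `phantom_grid`.
#' @export
phantom_grid <- function(material, dx, properties = phantom_properties(),
                         boundary = list(type = "insulated"),
                         initial_temp = 25) {
  if (!is.matrix(material) || !is.character(material)) {
    stop_argument("`material` must be a character matrix")
  }
  labs <- unique(as.vector(material))
  missing_props <- setdiff(labs, names(properties))
  if (length(missing_props)) {
    stop_argument(paste("missing thermal properties for:",
                        paste(missing_props, collapse = ", ")))
  }
  k <- rho_c <- matrix(0, nrow(material), ncol(material))
  for (lab in labs) {
    sel <- material == lab
    k[sel] <- properties[[lab]]$k
    rho_c[sel] <- properties[[lab]]$rho_c
  }
  if (any(k <= 0) || any(rho_c <= 0)) {
    stop_argument("conductivity and volumetric heat capacity must be > 0")
  }
  if (!boundary$type %in% c("insulated", "convective")) {
    stop_argument("boundary type must be 'insulated' or 'convective'")
  }
  temps <- if (is.matrix(initial_temp)) {
    if (!identical(dim(initial_temp), dim(material))) {
      stop_argument("`initial_temp` matrix must match the grid shape")
    }
    initial_temp
  } else {
    matrix(initial_temp, nrow(material), ncol(material))
  }
  structure(
    list(
      ny = nrow(material), nx = ncol(material), dx = dx,
      material = material, k = k, rho_c = rho_c,
      inclusion = material == "inclusion",
      boundary = boundary, temps = temps
    ),
    class = "phantom_grid"
  )
}

#' Default phantom thermal properties
#'
#' Agarose hydrogel layers are thermally water-like; the optical additives
#' (intralipid scatterer, melanoidin pigment) are collapsed into the beam's
#' absorbed fraction and do not alter conduction.
#'
#' @param k Thermal conductivity in W/(m °C) (default 0.6, water).
#' @param rho_c Volumetric heat capacity in J/(m^3 °C) (default 4.18e6,
#'   water).
#' @return Named list of per-material properties.
#' @export
phantom_properties <- function(k = 0.6, rho_c = 4.18e6) {
  props <- list(k = k, rho_c = rho_c)
  list(dermal = props, epidermal = props, inclusion = props)
}

#' Build the two-layer skin phantom
#'
#' Cross-section grid with the irradiated epidermal band on top (default
#' 4 mm), the dermal band below (default 8 mm, extended to fill any extra
#' grid depth), and a nanoparticle-doped inclusion of `inclusion_width_mm`
#' punched centrally into the epidermal band.
#'
#' @param nx,ny Grid size: `nx` columns (width), `ny` rows (depth).
#' @param dx_mm Cell size in mm (default 0.25).
#' @param epidermal_mm,dermal_mm Layer thicknesses in mm.
#' @param inclusion_width_mm Inclusion width in mm (> 0); default 1.25.
#' @param inclusion_depth_mm Inclusion depth in mm; defaults to the full
#'   epidermal thickness and may not exceed it.
#' @param properties,boundary,initial_temp Passed to [phantom_grid()].  A
#'   pre-cooled phantom is obtained by lowering `initial_temp`.
#' @return A [phantom_grid()].
#' @examples
#' g <- build_phantom()
#' sum(g$inclusion[1, ])  # inclusion spans 5 cells at dx = 0.25 mm
#' @export
build_phantom <- function(nx = 96, ny = 64, dx_mm = 0.25,
                          epidermal_mm = 4, dermal_mm = 8,
                          inclusion_width_mm = 1.25,
                          inclusion_depth_mm = NULL,
                          properties = phantom_properties(),
                          boundary = list(type = "insulated"),
                          initial_temp = 25) {
  if (!is_scalar_number(inclusion_width_mm) || inclusion_width_mm <= 0) {
    stop_argument("`inclusion_width_mm` must be > 0")
  }
  if (is.null(inclusion_depth_mm)) inclusion_depth_mm <- epidermal_mm
  if (inclusion_depth_mm > epidermal_mm) {
    stop_argument("inclusion may not extend deeper than the epidermal layer")
  }
  depth_mm <- ny * dx_mm
  if (depth_mm < epidermal_mm + dermal_mm - 1e-9) {
    stop_argument(sprintf(
      "grid depth %.3g mm is shallower than epidermal + dermal = %.3g mm",
      depth_mm, epidermal_mm + dermal_mm
    ))
  }
  n_epi <- round(epidermal_mm / dx_mm)
  w_cells <- max(1L, round(inclusion_width_mm / dx_mm))
  if (w_cells > nx) stop_argument("inclusion wider than the grid")
  d_cells <- max(1L, round(inclusion_depth_mm / dx_mm))

  material <- matrix("dermal", ny, nx)
  material[seq_len(n_epi), ] <- "epidermal"
  c0 <- ceiling(nx / 2)
  cols <- seq(c0 - floor((w_cells - 1) / 2), length.out = w_cells)
  material[seq_len(d_cells), cols] <- "inclusion"

  phantom_grid(material, dx = dx_mm * 1e-3, properties = properties,
               boundary = boundary, initial_temp = initial_temp)
}

#' @export
print.phantom_grid <- function(x, ...) {
  cat(sprintf("Phantom grid: %d x %d cells, dx = %.3g mm (%g x %g mm)\n",
              x$ny, x$nx, x$dx * 1e3, x$ny * x$dx * 1e3, x$nx * x$dx * 1e3))
  cat(sprintf("  inclusion: %d cells; boundary: %s\n",
              sum(x$inclusion), x$boundary$type))
  invisible(x)
}

#' Construct a beam source
#'
#' @param power Incident laser power I in watts (>= 0).
#' @param absorbed_fraction Fraction of incident light absorbed by the
#'   inclusion, `1 - 10^(-A)` for optical density A; in \[0, 1\].
#' @param efficiency Photothermal conversion efficiency of the dopant in
#'   \[0, 1\].
#' @param spot_diameter_mm Beam spot diameter in mm (1/e^2), default 3.
#' @param center_col Column of the beam axis; defaults to the inclusion
#'   centroid at simulation time.
#' @return Object of class `beam_source`.
#' @export
beam_source <- function(power, absorbed_fraction = 1, efficiency = 1,
                        spot_diameter_mm = 3, center_col = NULL) {
  if (!is_scalar_number(power) || power < 0) stop_argument("`power` must be >= 0")
  if (!is_scalar_number(absorbed_fraction) ||
      absorbed_fraction < 0 || absorbed_fraction > 1) {
    stop_argument("`absorbed_fraction` must lie in [0, 1]")
  }
  if (!is_scalar_number(efficiency) || efficiency < 0 || efficiency > 1) {
    stop_argument("`efficiency` must lie in [0, 1]")
  }
  if (!is_scalar_number(spot_diameter_mm) || spot_diameter_mm <= 0) {
    stop_argument("`spot_diameter_mm` must be > 0")
  }
  structure(
    list(power = power, absorbed_fraction = absorbed_fraction,
         efficiency = efficiency, radius = spot_diameter_mm * 1e-3 / 2,
         center_col = center_col),
    class = "beam_source"
  )
}

#' Explicit-scheme stability limit
#'
#' Largest admissible time step of the forward-time central-space scheme,
#' `dx^2 * min(rho_c) / (4 * max(k))`.
#'
#' @param grid A [phantom_grid()].
#' @return Stability bound in seconds.
#' @export
stability_limit <- function(grid) {
  stopifnot(inherits(grid, "phantom_grid"))
  grid$dx^2 * min(grid$rho_c) / (4 * max(grid$k))
}

# Per-cell deposited power (W) for a beam over the inclusion: Gaussian
# lateral profile exp(-2 d^2 / r^2) about the beam axis, zero outside the
# inclusion, normalized to the total absorbed power.
source_field <- function(grid, beam) {
  total <- beam$power * beam$absorbed_fraction * beam$efficiency
  S <- matrix(0, grid$ny, grid$nx)
  if (total <= 0 || !any(grid$inclusion)) return(S)
  cc <- beam$center_col
  if (is.null(cc)) cc <- mean(which(grid$inclusion, arr.ind = TRUE)[, 2])
  d <- (col(S) - cc) * grid$dx
  w <- exp(-2 * d^2 / beam$radius^2)
  w[!grid$inclusion] <- 0
  S + w / sum(w) * total
}

#' Simulate laser heating of a phantom
#'
#' Forward-time central-space integration of the heat equation with the
#' beam's volumetric source, emitting thermogram frames every
#' `frame_interval` seconds (plus the initial frame) with optional additive
#' Gaussian camera noise.  The time step must respect the explicit-scheme
#' stability bound ([stability_limit()]); when `dt` is `NULL` a step of 90%
#' of the bound is used.  Internally the step is shortened so that an integer
#' number of steps fits each frame interval.
#'
#' @param grid A [phantom_grid()].
#' @param beam A [beam_source()].
#' @param duration Simulated time in seconds.
#' @param dt Time step in seconds, or `NULL` for automatic.
#' @param frame_interval Seconds between emitted frames (default 60, the
#'   1 frame/min camera cadence).
#' @param laser_off_at Time at which the source switches off (s), or `NULL`
#'   to keep it on for the whole run.
#' @param noise_sigma Additive Gaussian camera noise per pixel, °C.
#' @param seed RNG seed for the noise (ignored when `noise_sigma = 0`).
#' @return A [thermogram_stack()].  The attribute `"audit"` carries the
#'   discrete energy bookkeeping (`input_J`, `stored_J`, `boundary_loss_J`,
#'   see [energy_audit()]) and `"final_field"` the noiseless final
#'   temperature matrix.
#' @export
simulate_heating <- function(grid, beam, duration, dt = NULL,
                             frame_interval = 60, laser_off_at = NULL,
                             noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(grid, "phantom_grid"), inherits(beam, "beam_source"))
  if (!is_scalar_number(duration) || duration <= 0) {
    stop_argument("`duration` must be > 0")
  }
  if (!is_scalar_number(frame_interval) || frame_interval <= 0 ||
      frame_interval > duration) {
    stop_argument("`frame_interval` must lie in (0, duration]")
  }
  bound <- stability_limit(grid)
  if (is.null(dt)) dt <- 0.9 * bound
  if (!is_scalar_number(dt) || dt <= 0 || dt > bound) {
    stop_argument(sprintf(
      "time step dt = %.4g s violates the explicit stability bound %.4g s",
      dt, bound
    ))
  }
  steps_per_frame <- ceiling(frame_interval / dt)
  dt <- frame_interval / steps_per_frame
  n_frames <- floor(duration / frame_interval)

  ny <- grid$ny; nx <- grid$nx; dx <- grid$dx
  Temp <- grid$temps
  rho_c <- grid$rho_c
  S <- source_field(grid, beam)          # W per cell
  total_power <- sum(S)
  cap <- rho_c * dx^2                    # J/°C per cell (unit depth)

  # face conductivities (arithmetic mean), fixed through the run
  kV <- (grid$k[-1, , drop = FALSE] + grid$k[-ny, , drop = FALSE]) / 2
  kH <- (grid$k[, -1, drop = FALSE] + grid$k[, -nx, drop = FALSE]) / 2

  conv <- identical(grid$boundary$type, "convective")
  if (conv) {
    h_b <- grid$boundary$h
    T_ext <- grid$boundary$T_ext
    if (!is_scalar_number(h_b) || h_b < 0 || !is_scalar_number(T_ext)) {
      stop_argument("convective boundary needs `h` >= 0 and `T_ext`")
    }
  }

  input_J <- 0; boundary_loss_J <- 0
  frames <- vector("list", n_frames + 1L)
  stamps <- numeric(n_frames + 1L)
  frames[[1L]] <- Temp
  t_now <- 0

  for (fr in seq_len(n_frames)) {
    for (s in seq_len(steps_per_frame)) {
      net <- matrix(0, ny, nx)                           # W per cell
      fV <- kV * (Temp[-1, , drop = FALSE] - Temp[-ny, , drop = FALSE])
      net[-ny, ] <- net[-ny, ] + fV
      net[-1, ] <- net[-1, ] - fV
      fH <- kH * (Temp[, -1, drop = FALSE] - Temp[, -nx, drop = FALSE])
      net[, -nx] <- net[, -nx] + fH
      net[, -1] <- net[, -1] - fH
      if (conv && h_b > 0) {
        edge_loss <- 0
        for (edge in list(Temp[1, ], Temp[ny, ], Temp[, 1], Temp[, nx])) {
          edge_loss <- edge_loss + sum(edge - T_ext)
        }
        net[1, ] <- net[1, ] - h_b * dx * (Temp[1, ] - T_ext)
        net[ny, ] <- net[ny, ] - h_b * dx * (Temp[ny, ] - T_ext)
        net[, 1] <- net[, 1] - h_b * dx * (Temp[, 1] - T_ext)
        net[, nx] <- net[, nx] - h_b * dx * (Temp[, nx] - T_ext)
        boundary_loss_J <- boundary_loss_J + h_b * dx * edge_loss * dt
      }
      on <- is.null(laser_off_at) || t_now < laser_off_at
      if (on && total_power > 0) {
        net <- net + S
        input_J <- input_J + total_power * dt
      }
      Temp <- Temp + dt * net / cap
      t_now <- t_now + dt
    }
    frames[[fr + 1L]] <- Temp
    stamps[fr + 1L] <- t_now
  }

  stored_J <- sum(cap * (Temp - grid$temps))
  if (noise_sigma > 0) {
    frames <- with_seed(seed, lapply(frames, function(f) {
      f + matrix(stats::rnorm(length(f), sd = noise_sigma), nrow(f), ncol(f))
    }))
  }

  amb <- if (is.matrix(grid$temps)) mean(grid$temps) else grid$temps
  stack <- thermogram_stack(
    frames = frames, timestamps = stamps, pixel_pitch_mm = dx * 1e3,
    ambient_temp = amb, laser_on_s = 0,
    laser_off_s = if (is.null(laser_off_at)) NA else laser_off_at
  )
  attr(stack, "audit") <- list(
    input_J = input_J, stored_J = stored_J, boundary_loss_J = boundary_loss_J
  )
  attr(stack, "final_field") <- Temp
  stack
}

#' Energy audit of a simulation
#'
#' Discrete energy bookkeeping of a [simulate_heating()] run: the deposited
#' laser energy should equal the stored enthalpy change plus the convective
#' boundary loss (exactly, up to round-off, for this flux-form scheme).
#'
#' @param stack A stack returned by [simulate_heating()].
#' @return List with `input_J`, `stored_J`, `boundary_loss_J`.
#' @export
energy_audit <- function(stack) {
  audit <- attr(stack, "audit")
  if (is.null(audit)) {
    stop_argument("stack carries no energy audit (not from simulate_heating?)")
  }
  audit
}

#' Calibrate the beam power for a target hotspot rise
#'
#' The heat equation is linear in the source, so a single unit-power run
#' fixes the power needed for any hotspot rise: runs the simulation with the
#' given beam, measures the maximum inclusion rise at `at_time`, and scales.
#' Exact for insulated boundaries and for convective boundaries with
#' `T_ext` equal to the initial temperature.
#'
#' @param grid A [phantom_grid()].
#' @param beam A [beam_source()] (its power is the starting guess).
#' @param target_rise Desired hotspot rise in °C at `at_time`.
#' @param at_time Evaluation time in seconds.
#' @param dt,frame_interval Passed to [simulate_heating()].
#' @return A [beam_source()] with the calibrated power.
#' @export
calibrate_inclusion_power <- function(grid, beam, target_rise, at_time,
                                      dt = NULL, frame_interval = at_time) {
  stopifnot(inherits(grid, "phantom_grid"), inherits(beam, "beam_source"))
  if (!is_scalar_number(target_rise) || target_rise <= 0) {
    stop_argument("`target_rise` must be > 0")
  }
  run <- simulate_heating(grid, beam, duration = at_time, dt = dt,
                          frame_interval = frame_interval)
  final <- attr(run, "final_field")
  rise <- max(final[grid$inclusion] - grid$temps[grid$inclusion])
  if (rise <= 0) stop_calibration("unit run produced no hotspot rise")
  beam_source(
    power = beam$power * target_rise / rise,
    absorbed_fraction = beam$absorbed_fraction,
    efficiency = beam$efficiency,
    spot_diameter_mm = beam$radius * 2e3,
    center_col = beam$center_col
  )
}
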