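# Extinction spectra: LSPR band location and optical density extraction.
#
# Triangular gold nanoparticles show two dipolar plasmon bands: an
# out-of-plane resonance in the visible (overlapping the ~534 nm band of
# co-synthesized nanospheres) and a size-tunable in-plane resonance in the
# NIR.  The optical density at the excitation wavelength enters the
# efficiency energy balance through the absorbed fraction 1 - 10^(-A).

#' Construct a spectrum record
#'
#' @param wavelengths Wavelengths in nm, strictly increasing, within
#'   \[300, 1400\] nm, at least 10 points.
#' @param extinction Optical densities, same length.
#' @param label Optional sample label.
#' @return Object of class `spectrum_record`.
#' @export
spectrum_record <- function(wavelengths, extinction, label = "") {
  wavelengths <- as.numeric(wavelengths)
  extinction <- as.numeric(extinction)
  if (length(wavelengths) != length(extinction) || length(wavelengths) < 10L) {
    stop_argument("need >= 10 (wavelength, extinction) pairs of equal length")
  }
  if (any(diff(wavelengths) <= 0)) {
    stop_argument("`wavelengths` must be strictly increasing")
  }
  if (min(wavelengths) < 300 || max(wavelengths) > 1400) {
    stop_argument("`wavelengths` must lie within [300, 1400] nm")
  }
  if (any(!is.finite(extinction))) stop_argument("`extinction` must be finite")
  structure(
    list(wavelengths = wavelengths, extinction = extinction,
         label = as.character(label)),
    class = "spectrum_record"
  )
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf("Extinction spectrum%s: %d points, %.0f-%.0f nm, OD %.3g-%.3g\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              min(x$extinction), max(x$extinction)))
  invisible(x)
}

# Topographic prominence of every interior local maximum of y: the height of
# the peak above the higher of the two bounding valleys, where each valley is
# the minimum between the peak and the nearest higher point (or series end).
peak_prominences <- function(y) {
  n <- length(y)
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  prom <- vapply(idx, function(i) {
    h <- y[i]
    left_min <- h
    j <- i - 1L
    while (j >= 1L && y[j] <= h) {
      left_min <- min(left_min, y[j]); j <- j - 1L
    }
    right_min <- h
    j <- i + 1L
    while (j <= n && y[j] <= h) {
      right_min <- min(right_min, y[j]); j <- j + 1L
    }
    h - max(left_min, right_min)
  }, numeric(1))
  list(index = idx, prominence = prom)
}

#' Locate the out-of-plane and in-plane LSPR bands
#'
#' Finds local maxima by topographic prominence and assigns the most
#' prominent peak in the 450-620 nm window to the out-of-plane (or
#' nanosphere) band and the most prominent in 620-1300 nm to the in-plane
#' band.  A band is reported absent when no peak in its window reaches the
#' prominence threshold.
#'
#' @param spectrum A [spectrum_record()].
#' @param prominence Minimum peak prominence in OD (default 0.02).
#' @param out_window,in_window Wavelength windows in nm.
#' @return Object of class `lspr_peaks` with fields `out_of_plane_nm`,
#'   `in_plane_nm` (NA when absent), and `in_plane_od`.
#' @export
find_lspr_peaks <- function(spectrum, prominence = 0.02,
                            out_window = c(450, 620),
                            in_window = c(620, 1300)) {
  stopifnot(inherits(spectrum, "spectrum_record"))
  pk <- peak_prominences(spectrum$extinction)
  wl <- spectrum$wavelengths[pk$index]
  keep <- pk$prominence >= prominence

  pick <- function(window) {
    in_win <- keep & wl >= window[1] & wl <= window[2]
    if (!any(in_win)) return(NA_integer_)
    pk$index[in_win][which.max(pk$prominence[in_win])]
  }
  i_out <- pick(out_window)
  i_in <- pick(in_window)
  structure(
    list(
      out_of_plane_nm = if (is.na(i_out)) NA_real_ else spectrum$wavelengths[i_out],
      in_plane_nm = if (is.na(i_in)) NA_real_ else spectrum$wavelengths[i_in],
      in_plane_od = if (is.na(i_in)) NA_real_ else spectrum$extinction[i_in]
    ),
    class = "lspr_peaks"
  )
}

#' @export
print.lspr_peaks <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "<absent>" else sprintf("%.0f nm", v)
  cat(sprintf("LSPR bands: out-of-plane %s, in-plane %s",
              fmt(x$out_of_plane_nm), fmt(x$in_plane_nm)))
  if (!is.na(x$in_plane_od)) cat(sprintf(" (OD %.3f)", x$in_plane_od))
  cat("\n")
  invisible(x)
}

#' Optical density at a wavelength
#'
#' Linear interpolation between the bracketing samples; exact at sample
#' points.  At 1 nm instrument resolution higher-order interpolation gains
#' nothing.
#'
#' @param spectrum A [spectrum_record()].
#' @param wavelength Query wavelength in nm, within the recorded range.
#' @return Optical density (OD).
#' @export
od_at_wavelength <- function(spectrum, wavelength) {
  stopifnot(inherits(spectrum, "spectrum_record"))
  if (!is_scalar_number(wavelength) ||
      wavelength < min(spectrum$wavelengths) ||
      wavelength > max(spectrum$wavelengths)) {
    stop_argument(sprintf(
      "wavelength %.1f nm outside recorded range [%.1f, %.1f] nm",
      wavelength, min(spectrum$wavelengths), max(spectrum$wavelengths)
    ))
  }
  stats::approx(spectrum$wavelengths, spectrum$extinction,
                xout = wavelength, method = "linear")$y
}

#' Rescale a spectrum to a target in-plane optical density
#'
#' Multiplies the whole spectrum by `target_od / in_plane_od` so that the
#' in-plane LSPR band reaches `target_od`, leaving peak positions and band
#' shape unchanged (the concentration-normalization step applied before
#' thermal experiments).
#'
#' @param spectrum A [spectrum_record()].
#' @param target_od Target OD of the in-plane band (default 0.56).
#' @return A rescaled [spectrum_record()].
#' @export
normalize_to_od <- function(spectrum, target_od = 0.56) {
  stopifnot(inherits(spectrum, "spectrum_record"))
  if (!is_scalar_number(target_od) || target_od <= 0) {
    stop_argument("`target_od` must be > 0")
  }
  peaks <- find_lspr_peaks(spectrum)
  if (is.na(peaks$in_plane_nm)) {
    stop_argument("no detectable in-plane LSPR band to normalize to")
  }
  spectrum_record(
    spectrum$wavelengths,
    spectrum$extinction * (target_od / peaks$in_plane_od),
    label = spectrum$label
  )
}
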