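# Plain-text on-disk formats for every pipeline input.
#
#   thermal trace   : CSV (time_s,temp_C) + JSON sidecar with the metadata
#   spectrum        : CSV (wavelength_nm,extinction)
#   thermogram stack: directory of frame_0001.csv ... (row-major matrices,
#                     no header) + manifest.json
#   MTT plate       : CSV (well,group,od570,od670,irradiated)

#' Write / read a thermal trace
#'
#' The trace samples go to a two-column CSV (`time_s`, `temp_C`); ambient
#' temperature, laser phase times, and any scalar metadata (laser power,
#' absorbance, components) go to a JSON sidecar.
#'
#' @param trace A [thermal_trace()].
#' @param csv_path Path of the CSV file.
#' @param meta_path Path of the JSON sidecar; defaults to `csv_path` with a
#'   `.json` extension.
#' @return `write_thermal_trace()` returns `csv_path` invisibly;
#'   `read_thermal_trace()` returns a [thermal_trace()].
#' @export
write_thermal_trace <- function(trace, csv_path,
                                meta_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(trace, "thermal_trace"))
  utils::write.csv(as.data.frame(trace), csv_path, row.names = FALSE)
  meta <- list(
    ambient_temp_C = trace$ambient_temp,
    laser_on_s = trace$laser_on_time,
    laser_off_s = if (is.na(trace$laser_off_time)) NULL else trace$laser_off_time
  )
  extra <- trace$metadata[
    vapply(trace$metadata, function(v) is.atomic(v) || is.data.frame(v) ||
             (is.list(v) && !is.environment(v)), logical(1))
  ]
  extra$params <- NULL; extra$ground_truth <- NULL; extra$noise <- NULL
  jsonlite::write_json(c(meta, extra), meta_path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(csv_path)
}

#' @rdname write_thermal_trace
#' @export
read_thermal_trace <- function(csv_path,
                               meta_path = sub("\\.csv$", ".json", csv_path)) {
  df <- utils::read.csv(csv_path)
  if (!all(c("time_s", "temp_C") %in% names(df))) {
    stop_argument("trace CSV must have columns time_s,temp_C")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  thermal_trace(
    times = df$time_s, temps = df$temp_C,
    ambient_temp = meta$ambient_temp_C,
    laser_on_time = if (is.null(meta$laser_on_s)) 0 else meta$laser_on_s,
    laser_off_time = if (is.null(meta$laser_off_s)) NA else meta$laser_off_s,
    metadata = meta[setdiff(names(meta),
                            c("ambient_temp_C", "laser_on_s", "laser_off_s"))]
  )
}

#' Write / read an extinction spectrum
#'
#' @param spectrum A [spectrum_record()].
#' @param path CSV path (`wavelength_nm`, `extinction`).
#' @param label Label assigned on read.
#' @return The path (write, invisibly) or a [spectrum_record()] (read).
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum_record"))
  utils::write.csv(
    data.frame(wavelength_nm = spectrum$wavelengths,
               extinction = spectrum$extinction),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path, label = "") {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "extinction") %in% names(df))) {
    stop_argument("spectrum CSV must have columns wavelength_nm,extinction")
  }
  spectrum_record(df$wavelength_nm, df$extinction, label = label)
}

#' Write / read a thermogram stack directory
#'
#' Each frame is stored as `frame_0001.csv`, ... (comma-separated matrix
#' rows, no header) next to a `manifest.json` holding `timestamps_s`,
#' `pixel_pitch_mm`, `ambient_temp_C`, and the laser phase annotations.
#'
#' @param stack A [thermogram_stack()].
#' @param dir Directory path (created if needed).
#' @return The directory (write, invisibly) or a [thermogram_stack()]
#'   (read).
#' @export
write_thermogram_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "thermogram_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$frames)) {
    utils::write.table(
      stack$frames[[i]], file.path(dir, sprintf("frame_%04d.csv", i)),
      sep = ",", row.names = FALSE, col.names = FALSE
    )
  }
  jsonlite::write_json(
    list(
      timestamps_s = stack$timestamps,
      pixel_pitch_mm = stack$pixel_pitch_mm,
      ambient_temp_C = stack$ambient_temp,
      laser_on_s = stack$laser_on_s,
      laser_off_s = if (is.na(stack$laser_off_s)) NULL else stack$laser_off_s
    ),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null"
  )
  invisible(dir)
}

#' @rdname write_thermogram_stack
#' @export
read_thermogram_stack <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop_argument(sprintf("no manifest.json in '%s'", dir))
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L) stop_argument("no frame_*.csv files in stack directory")
  frames <- lapply(files, function(f) {
    as.matrix(utils::read.table(f, sep = ",", header = FALSE))
  })
  frames <- lapply(frames, unname)
  thermogram_stack(
    frames = frames,
    timestamps = manifest$timestamps_s,
    pixel_pitch_mm = manifest$pixel_pitch_mm,
    ambient_temp = manifest$ambient_temp_C,
    laser_on_s = if (is.null(manifest$laser_on_s)) 0 else manifest$laser_on_s,
    laser_off_s = if (is.null(manifest$laser_off_s)) NA else manifest$laser_off_s
  )
}

#' Write / read an MTT plate table
#'
#' @param plate An [mtt_plate()].
#' @param path CSV path (`well,group,od570,od670,irradiated`).
#' @return The path (write, invisibly) or an [mtt_plate()] (read).
#' @export
write_mtt_plate <- function(plate, path) {
  stopifnot(inherits(plate, "mtt_plate"))
  utils::write.csv(plate$wells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mtt_plate
#' @export
read_mtt_plate <- function(path) {
  mtt_plate(utils::read.csv(path))
}
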