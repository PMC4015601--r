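#' Read a thermal frame from a delimited text matrix
#'
#' Reads one rectangular numeric matrix of temperatures (degrees C) from a
#' delimited text file (CSV by default). Ragged rows and non-numeric cells
#' are reported with their position rather than silently coerced.
#'
#' @param path Path to the text file.
#' @param delimiter Field separator, default `","`.
#' @param ... Passed to [thermal_frame()] (e.g. `frame_index`, `timestamp`).
#'
#' @return A [thermal_frame()].
#' @export
read_frame_matrix <- function(path, delimiter = ",", ...) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop(sprintf("format error: %s is empty", path), call. = FALSE)
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    stop(sprintf(
      "format error: ragged rows in %s (row 1 has %d fields, row %d has %d)",
      path, widths[1], which(widths != widths[1])[1],
      widths[which(widths != widths[1])[1]]), call. = FALSE)
  vals <- suppressWarnings(lapply(cells, function(r) as.numeric(trimws(r))))
  for (i in seq_along(vals)) {
    bad <- which(is.na(vals[[i]]) & trimws(cells[[i]]) != "NA")
    if (length(bad) > 0L)
      stop(sprintf("parse error: non-numeric cell '%s' at row %d, column %d of %s",
                   trimws(cells[[i]][bad[1]]), i, bad[1], path), call. = FALSE)
  }
  m <- do.call(rbind, vals)
  thermal_frame(m, ...)
}

#' Write a thermal frame as a delimited text matrix
#'
#' @param frame A [thermal_frame()] or plain numeric matrix.
#' @param path Output path.
#' @param delimiter Field separator, default `","`.
#' @return `path`, invisibly.
#' @export
write_frame_matrix <- function(frame, path, delimiter = ",") {
  values <- if (inherits(frame, "thermal_frame")) frame$values else frame
  rows <- apply(values, 1L, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = delimiter))
  writeLines(rows, path)
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

#' Read a thermal sequence from a multi-page 16-bit TIFF
#'
#' Pages become frames in order; each pixel temperature is
#' `count * scale + offset` in degrees C. If `scale` is missing, a YAML
#' sidecar (`<basename>.yaml` with keys `scale`, `offset`, `frame_rate`)
#' written by [write_sequence_tiff()] is consulted.
#'
#' @param path Path to a multi-page 16-bit grayscale TIFF.
#' @param scale Degrees C per count.
#' @param offset Degrees C at count 0.
#' @param frame_rate Frames per second; sidecar value used if missing.
#'
#' @return A [thermal_sequence()].
#' @export
read_sequence_tiff <- function(path, scale = NULL, offset = NULL,
                               frame_rate = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  sc <- sidecar_path(path)
  if ((is.null(scale) || is.null(offset) || is.null(frame_rate)) &&
      file.exists(sc)) {
    meta <- yaml::read_yaml(sc)
    if (is.null(scale)) scale <- meta$scale
    if (is.null(offset)) offset <- meta$offset
    if (is.null(frame_rate)) frame_rate <- meta$frame_rate
  }
  if (is.null(scale) || is.null(offset))
    stop("`scale` and `offset` must be given (or present in the YAML sidecar)",
         call. = FALSE)
  if (is.null(frame_rate)) frame_rate <- 25
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop(sprintf("format error: cannot read TIFF %s (%s)",
                                   path, conditionMessage(e)), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, is.matrix, logical(1))))
    stop("format error: non-grayscale TIFF page (expected single-channel)",
         call. = FALSE)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("format error: TIFF pages have mixed sizes", call. = FALSE)
  frames <- lapply(seq_along(pages), function(i)
    thermal_frame(pages[[i]] * scale + offset,
                  timestamp = (i - 1) / frame_rate, frame_index = i - 1L))
  thermal_sequence(frames, frame_rate = frame_rate)
}

#' Write a thermal sequence as a multi-page 16-bit TIFF with YAML sidecar
#'
#' Temperatures are quantized to `round((T - offset) / scale)` 16-bit counts,
#' so the round-trip error is at most `scale / 2` degrees C. A YAML sidecar
#' recording `scale`, `offset` and `frame_rate` is written next to the TIFF.
#'
#' @param seq A [thermal_sequence()].
#' @param path Output TIFF path.
#' @param scale Degrees C per count (default 0.01, i.e. 10 mK quantization).
#' @param offset Degrees C at count 0.
#' @param sidecar Write the YAML sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_sequence_tiff <- function(seq, path, scale = 0.01, offset = 0,
                                sidecar = TRUE) {
  stopifnot(inherits(seq, "thermal_sequence"))
  pages <- lapply(seq$frames, function(f) {
    counts <- round((f$values - offset) / scale)
    if (min(counts) < 0 || max(counts) > 65535)
      stop(sprintf(
        "temperatures out of 16-bit range for scale=%g, offset=%g (counts %g-%g)",
        scale, offset, min(counts), max(counts)), call. = FALSE)
    counts / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (sidecar)
    yaml::write_yaml(list(scale = scale, offset = offset,
                          frame_rate = seq$frame_rate), sidecar_path(path))
  invisible(path)
}

#' Radiometric calibration parameters
#'
#' Parameters of the radiance balance used to convert the camera's apparent
#' temperature reading into the true object surface temperature. The defaults
#' describe the neonatal-incubator setting: skin emissivity 0.972, infrared
#' transmission of the polyethylene foil window 0.93 (mid-range of the
#' 0.92-0.94 material band), and a camera that registered readings against
#' emissivity 1 (skin treated as a blackbody at acquisition time).
#'
#' @param emissivity Object surface emissivity, in (0, 1].
#' @param foil_transmission IR transmission of the window between camera and
#'   object, in (0, 1]. Use 1 when imaging directly.
#' @param ambient_temperature Reflected ambient (incubator air) temperature,
#'   degrees C.
#' @param foil_temperature Temperature of the foil window, degrees C;
#'   defaults to the ambient temperature.
#' @param registered_emissivity Emissivity the camera assumed when converting
#'   radiance to its displayed temperature (default 1).
#'
#' @return An object of class `calibration_config`.
#' @examples
#' cal <- calibration_config()
#' correct_temperature(36, cal)
#' @export
calibration_config <- function(emissivity = 0.972,
                               foil_transmission = 0.93,
                               ambient_temperature = 34,
                               foil_temperature = ambient_temperature,
                               registered_emissivity = 1) {
  if (emissivity <= 0 || emissivity > 1)
    stop("`emissivity` must be in (0, 1]", call. = FALSE)
  if (foil_transmission <= 0 || foil_transmission > 1)
    stop("`foil_transmission` must be in (0, 1]", call. = FALSE)
  if (registered_emissivity <= 0 || registered_emissivity > 1)
    stop("`registered_emissivity` must be in (0, 1]", call. = FALSE)
  structure(list(emissivity = emissivity,
                 foil_transmission = foil_transmission,
                 ambient_temperature = ambient_temperature,
                 foil_temperature = foil_temperature,
                 registered_emissivity = registered_emissivity),
            class = "calibration_config")
}

# blackbody band radiance proxy, W(T) ~ (T + 273.15)^4 (Stefan-Boltzmann,
# constant of proportionality cancels in the balance)
radiance <- function(temp_c) (temp_c + 273.15)^4

#' Correct an apparent temperature reading for emissivity and transmission
#'
#' Inverts the radiance balance
#' \deqn{W_{meas} = \tau\,\epsilon\,W(T_{obj}) + \tau(1-\epsilon)W(T_{amb})
#'   + (1-\tau)W(T_{foil}),\qquad W(T) \propto (T + 273.15)^4,}
#' where the measured radiance is reconstructed from the camera's apparent
#' reading under the emissivity the camera was registered with (unit
#' transmission): \eqn{W_{meas} = \epsilon_r W(T_{app}) +
#' (1-\epsilon_r)W(T_{amb})}. With \eqn{\epsilon = \tau = \epsilon_r = 1}
#' the correction is the identity.
#'
#' @param apparent Apparent temperature reading(s), degrees C. Vectorized.
#' @param cal A [calibration_config()].
#'
#' @return Corrected object temperature(s), degrees C.
#' @export
correct_temperature <- function(apparent, cal) {
  stopifnot(inherits(cal, "calibration_config"))
  w_meas <- cal$registered_emissivity * radiance(apparent) +
    (1 - cal$registered_emissivity) * radiance(cal$ambient_temperature)
  tau <- cal$foil_transmission
  eps <- cal$emissivity
  w_obj <- (w_meas -
              tau * (1 - eps) * radiance(cal$ambient_temperature) -
              (1 - tau) * radiance(cal$foil_temperature)) / (tau * eps)
  if (any(w_obj <= 0))
    stop("domain error: non-positive object radiance (nonphysical parameter combination)",
         call. = FALSE)
  w_obj^0.25 - 273.15
}
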