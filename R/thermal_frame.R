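#' Construct a thermal frame
#'
#' A thermal frame is one 2-D grid of temperatures (degrees Celsius) together
#' with acquisition metadata. Values must be finite; values outside a
#' configurable plausibility range (default 5-60 degrees C, covering clinical
#' incubator scenes) trigger a warning, never an error, so that unusual but
#' valid scenes are not rejected.
#'
#' @param values Numeric matrix of temperatures in degrees C, at least 2x2.
#' @param timestamp Seconds from sequence start.
#' @param frame_index Non-negative integer position in the sequence.
#' @param plausible_range Length-2 numeric; values outside it warn.
#'
#' @return An object of class `thermal_frame`: a list with elements
#'   `values`, `timestamp`, `frame_index`.
#' @examples
#' fr <- thermal_frame(matrix(34, 4, 4))
#' dim(fr$values)
#' @export
thermal_frame <- function(values, timestamp = 0, frame_index = 0L,
                          plausible_range = c(5, 60)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("frame must be at least 2x2 pixels", call. = FALSE)
  if (!all(is.finite(values)))
    stop("frame contains non-finite temperatures", call. = FALSE)
  if (length(frame_index) != 1L || frame_index < 0)
    stop("`frame_index` must be a single non-negative integer", call. = FALSE)
  if (!is.null(plausible_range) &&
      (min(values) < plausible_range[1] || max(values) > plausible_range[2]))
    warning(sprintf(
      "temperatures outside plausible range [%g, %g] degC (frame range %.2f-%.2f)",
      plausible_range[1], plausible_range[2], min(values), max(values)),
      call. = FALSE)
  structure(
    list(values = values, timestamp = as.numeric(timestamp),
         frame_index = as.integer(frame_index)),
    class = "thermal_frame")
}

#' @export
print.thermal_frame <- function(x, ...) {
  cat(sprintf("<thermal_frame> %d x %d px, t = %.3f s, index %d, %.2f-%.2f degC\n",
              nrow(x$values), ncol(x$values), x$timestamp, x$frame_index,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a thermal sequence
#'
#' An ordered list of [thermal_frame()] objects sharing one grid size,
#' acquired at a fixed frame rate.
#'
#' @param frames List of `thermal_frame` objects with identical dimensions
#'   and strictly increasing `frame_index`.
#' @param frame_rate Frames per second (default 25, a typical clinical
#'   acquisition rate).
#'
#' @return An object of class `thermal_sequence`.
#' @export
thermal_sequence <- function(frames, frame_rate = 25) {
  if (length(frames) == 0L)
    stop("sequence must contain at least one frame", call. = FALSE)
  if (!all(vapply(frames, inherits, logical(1), "thermal_frame")))
    stop("all elements of `frames` must be thermal_frame objects", call. = FALSE)
  dims <- vapply(frames, function(f) dim(f$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share identical dimensions", call. = FALSE)
  idx <- vapply(frames, `[[`, integer(1), "frame_index")
  if (length(idx) > 1L && any(diff(idx) <= 0L))
    stop("frame_index must be strictly increasing", call. = FALSE)
  if (frame_rate <= 0)
    stop("`frame_rate` must be positive", call. = FALSE)
  structure(list(frames = frames, frame_rate = as.numeric(frame_rate)),
            class = "thermal_sequence")
}

#' @export
print.thermal_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]]$values)
  cat(sprintf("<thermal_sequence> %d frames of %d x %d px @ %g fps\n",
              length(x$frames), d[1], d[2], x$frame_rate))
  invisible(x)
}

#' @export
length.thermal_sequence <- function(x) length(x$frames)
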