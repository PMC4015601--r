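#' Tracking run configuration
#'
#' Collects every tunable of the tracking pipeline in one validated object.
#'
#' @param matcher Matching mode: `"rpt"` (ring projection transform,
#'   rotation-invariant), `"parametric"` (multi-scale RPT with
#'   Lagrange-multiplier weights, adds a scale estimate), or `"ncc"`
#'   (raw-pixel normalized cross-correlation baseline).
#' @param window Search half-width in pixels around the previous position
#'   (default 12). A full-frame search is used while a ROI is lost.
#' @param threshold Acceptance threshold in NC units (default 50); a frame
#'   whose peak score falls below it is a miss.
#' @param patience Consecutive misses before a ROI is declared lost
#'   (default 10).
#' @param scales Scale grid for the parametric matcher.
#' @param tolerance_px Position-error tolerance (pixels) for evaluation.
#' @param tracked_threshold Per-ROI success rate (percent) at or above which
#'   a ROI counts as "fitting and tracked" rather than misallocated in the
#'   region-level report.
#' @param calibration A [calibration_config()].
#' @param rois Optional data frame of ROI specs (columns `roi`, `label`,
#'   `x`, `y`, `height`, `width`) used by the command-line pipeline.
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(matcher = c("rpt", "parametric", "ncc"),
                       window = 12L,
                       threshold = 50,
                       patience = 10L,
                       scales = c(0.8, 0.9, 1.0, 1.1, 1.2),
                       tolerance_px = 2L,
                       tracked_threshold = 50,
                       calibration = calibration_config(),
                       rois = NULL) {
  matcher <- match.arg(matcher)
  if (window < 1) stop("`window` must be >= 1", call. = FALSE)
  if (threshold < -100 || threshold > 100)
    stop("`threshold` must be in [-100, 100] NC units", call. = FALSE)
  if (patience < 1) stop("`patience` must be >= 1", call. = FALSE)
  if (tolerance_px < 0) stop("`tolerance_px` must be >= 0", call. = FALSE)
  if (tracked_threshold < 0 || tracked_threshold > 100)
    stop("`tracked_threshold` must be in [0, 100]", call. = FALSE)
  stopifnot(inherits(calibration, "calibration_config"))
  structure(list(matcher = matcher, window = as.integer(window),
                 threshold = threshold, patience = as.integer(patience),
                 scales = scales, tolerance_px = as.integer(tolerance_px),
                 tracked_threshold = tracked_threshold,
                 calibration = calibration, rois = rois),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Reads the single-file YAML configuration of the tracking pipeline.
#' Unknown keys are rejected so that typos fail loudly instead of silently
#' falling back to defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  known <- c("matcher", "window", "threshold", "patience", "scales",
             "tolerance_px", "tracked_threshold", "calibration", "rois")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  args <- raw
  if (!is.null(raw$calibration)) {
    cal_known <- c("emissivity", "foil_transmission", "ambient_temperature",
                   "foil_temperature", "registered_emissivity")
    cal_unknown <- setdiff(names(raw$calibration), cal_known)
    if (length(cal_unknown) > 0L)
      stop(sprintf("unknown calibration key(s): %s",
                   paste(cal_unknown, collapse = ", ")), call. = FALSE)
    args$calibration <- do.call(calibration_config, raw$calibration)
  }
  if (!is.null(raw$rois)) {
    args$rois <- do.call(rbind, lapply(raw$rois, function(r) {
      # YAML 1.1 parses a bare `y` key as boolean TRUE; accept both
      yval <- if (!is.null(r$y)) r$y else r[["TRUE"]]
      if (is.null(yval))
        stop("ROI entry is missing its `y` coordinate", call. = FALSE)
      data.frame(roi = if (is.null(r$roi)) r$label else r$roi,
                 label = r$label, x = r$x, y = yval,
                 height = r$height, width = r$width)
    }))
  }
  if (!is.null(args$scales)) args$scales <- as.numeric(unlist(args$scales))
  do.call(run_config, args)
}
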