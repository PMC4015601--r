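#' Define tracked regions of interest on a reference frame
#'
#' Extracts the reference template of each ROI from frame 0 and builds its
#' matcher descriptor: the ring-projection signature (`"rpt"`), a
#' [parametric_template()] over the configured scale grid (`"parametric"`),
#' or the raw pixel vector (`"ncc"`). A ROI whose template has zero variance
#' carries no matchable structure and is rejected.
#'
#' @param frame0 Reference [thermal_frame()].
#' @param specs Data frame with columns `label`, `x`, `y` (top-left, 1-based,
#'   x = column), `height`, `width`, and optionally `roi` (unique id;
#'   defaults to a uniquified label).
#' @param config A [run_config()].
#' @return List of `roi_profile` objects.
#' @export
define_rois <- function(frame0, specs, config = run_config()) {
  stopifnot(inherits(frame0, "thermal_frame"), inherits(config, "run_config"))
  specs <- as.data.frame(specs)
  req <- c("label", "x", "y", "height", "width")
  if (!all(req %in% names(specs)))
    stop(sprintf("`specs` must have columns %s", paste(req, collapse = ", ")),
         call. = FALSE)
  if (is.null(specs$roi)) specs$roi <- make.unique(as.character(specs$label))
  if (anyDuplicated(specs$roi))
    stop("ROI ids must be unique", call. = FALSE)
  vals <- frame0$values
  lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    if (s$height < 3 || s$width < 3)
      stop(sprintf("ROI '%s' must be at least 3x3", s$roi), call. = FALSE)
    if (s$x < 1 || s$y < 1 ||
        s$x + s$width - 1 > ncol(vals) || s$y + s$height - 1 > nrow(vals))
      stop(sprintf("ROI '%s' extends outside the frame", s$roi), call. = FALSE)
    template <- vals[s$y:(s$y + s$height - 1), s$x:(s$x + s$width - 1),
                     drop = FALSE]
    if (sd(template) == 0)
      stop(sprintf("degenerate template: ROI '%s' has zero variance", s$roi),
           call. = FALSE)
    lut <- build_ring_lut(s$height, s$width)
    prof <- list(roi = as.character(s$roi), label = as.character(s$label),
                 x = as.integer(s$x), y = as.integer(s$y),
                 height = as.integer(s$height), width = as.integer(s$width),
                 matcher = config$matcher, template = template, lut = lut,
                 ref_rpt = ring_project(template, lut),
                 ref_vec = as.vector(template))
    if (config$matcher == "parametric")
      prof$ptemplate <- parametric_template(template, config$scales)
    structure(prof, class = "roi_profile")
  })
}

#' @export
print.roi_profile <- function(x, ...) {
  cat(sprintf("<roi_profile> '%s' (%s): %dx%d at (x=%d, y=%d), matcher %s\n",
              x$roi, x$label, x$height, x$width, x$x, x$y, x$matcher))
  invisible(x)
}

# score candidate top-left positions (row-major order expected) for one ROI;
# returns list(scores, scales). NA score = unmatchable (zero-variance window).
score_positions <- function(vals, roi, xs, ys) {
  ncand <- length(xs)
  hw <- roi$height * roi$width
  C <- matrix(0, hw, ncand)
  for (k in seq_len(ncand))
    C[, k] <- vals[ys[k]:(ys[k] + roi$height - 1L),
                   xs[k]:(xs[k] + roi$width - 1L)]
  if (roi$matcher == "ncc")
    return(list(scores = nc_columns(roi$ref_vec, C),
                scales = rep(NA_real_, ncand)))
  rpts <- roi$lut$proj %*% C
  if (roi$matcher == "rpt")
    return(list(scores = nc_columns(roi$ref_rpt, rpts),
                scales = rep(NA_real_, ncand)))
  # parametric: closed-form weight solve per candidate
  scores <- numeric(ncand); scales <- numeric(ncand)
  for (k in seq_len(ncand)) {
    m <- tryCatch(match_parametric(roi$ptemplate, rpts[, k]),
                  error = function(e) NULL)
    if (is.null(m)) { scores[k] <- NA_real_; scales[k] <- NA_real_ }
    else { scores[k] <- m$score; scales[k] <- m$scale }
  }
  list(scores = scores, scales = scales)
}

#' Search one frame for the best ROI match
#'
#' Evaluates the ROI's match score at every candidate top-left position
#' within `window` pixels of `position` (clipped to the frame; pass
#' `window = Inf` for a full-frame scan) and returns the arg-max. Ties at
#' the peak score are broken by smallest displacement from `position`, then
#' by row-major order, which keeps the tracker deterministic and
#' motion-continuity-preserving.
#'
#' @param frame A [thermal_frame()].
#' @param roi A `roi_profile` from [define_rois()].
#' @param position Previous top-left position `c(x, y)`; defaults to the
#'   ROI's reference position.
#' @param window Search half-width in pixels (`>= 1`), or `Inf`.
#' @return List with `x`, `y`, `score` (NC units, `-Inf` if no candidate
#'   was matchable) and `scale` (parametric matcher only, else `NA`).
#' @export
search_frame <- function(frame, roi, position = c(roi$x, roi$y), window = 12) {
  stopifnot(inherits(frame, "thermal_frame"), inherits(roi, "roi_profile"))
  if (!is.infinite(window) && window < 1)
    stop("`window` must be >= 1", call. = FALSE)
  vals <- frame$values
  xmax <- ncol(vals) - roi$width + 1L
  ymax <- nrow(vals) - roi$height + 1L
  if (xmax < 1L || ymax < 1L)
    stop("ROI is larger than the frame: empty candidate set", call. = FALSE)
  px <- position[1]; py <- position[2]
  xr <- if (is.infinite(window)) 1L:xmax else
    max(1L, px - window):min(xmax, px + window)
  yr <- if (is.infinite(window)) 1L:ymax else
    max(1L, py - window):min(ymax, py + window)
  # row-major candidate order: y varies slowest
  xs <- rep(xr, times = length(yr))
  ys <- rep(yr, each = length(xr))
  best <- list(x = NA_integer_, y = NA_integer_, score = -Inf,
               scale = NA_real_, disp2 = Inf)
  chunk <- 4096L
  for (from in seq(1L, length(xs), by = chunk)) {
    to <- min(from + chunk - 1L, length(xs))
    sc <- score_positions(vals, roi, xs[from:to], ys[from:to])
    s <- sc$scores
    s[is.na(s)] <- -Inf
    d2 <- (xs[from:to] - px)^2 + (ys[from:to] - py)^2
    for (k in seq_along(s)) {
      if (s[k] > best$score + 1e-9 ||
          (abs(s[k] - best$score) <= 1e-9 && d2[k] < best$disp2)) {
        best <- list(x = xs[from:to][k], y = ys[from:to][k], score = s[k],
                     scale = sc$scales[k], disp2 = d2[k])
      }
    }
  }
  best$disp2 <- NULL
  best
}

#' Track ROIs across a thermal sequence
#'
#' The per-frame loop of the virtual sensor: search for each ROI around its
#' previous position, accept the peak if its score reaches the acceptance
#' threshold, and extract the radiometrically corrected mean temperature
#' over the tracked window. On a miss the last position is held and the
#' record marked invalid; after `patience` consecutive misses the ROI is
#' declared lost and a full-frame search runs each frame until the score
#' recovers. The whole path is deterministic: identical inputs give
#' bit-identical trajectories.
#'
#' @param seq A [thermal_sequence()].
#' @param rois List of `roi_profile`s from [define_rois()].
#' @param config A [run_config()].
#' @return An object of class `tracking_result`: list with `trajectories`
#'   (data frame: `frame_index`, `roi`, `label`, `x`, `y`, `score`,
#'   `scale`, `valid`) and `readings` (data frame: `frame_index`, `roi`,
#'   `label`, `temperature_C`, `valid`; temperature is `NA` when the track
#'   is invalid).
#' @export
track_sequence <- function(seq, rois, config = run_config()) {
  stopifnot(inherits(seq, "thermal_sequence"), inherits(config, "run_config"))
  states <- lapply(rois, function(r)
    list(x = r$x, y = r$y, miss = 0L, lost = FALSE))
  n <- length(seq$frames)
  rows <- vector("list", n * length(rois))
  k <- 0L
  for (i in seq_len(n)) {
    frame <- seq$frames[[i]]
    for (j in seq_along(rois)) {
      roi <- rois[[j]]; st <- states[[j]]
      res <- search_frame(frame, roi, position = c(st$x, st$y),
                          window = if (st$lost) Inf else config$window)
      valid <- is.finite(res$score) && res$score >= config$threshold
      if (valid) {
        st$x <- res$x; st$y <- res$y; st$miss <- 0L; st$lost <- FALSE
      } else {
        st$miss <- st$miss + 1L
        if (st$miss >= config$patience) st$lost <- TRUE
      }
      states[[j]] <- st
      temp <- NA_real_
      if (valid) {
        win <- frame$values[st$y:(st$y + roi$height - 1L),
                            st$x:(st$x + roi$width - 1L)]
        temp <- mean(correct_temperature(win, config$calibration))
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        frame_index = frame$frame_index, roi = roi$roi, label = roi$label,
        x = st$x, y = st$y, score = res$score, scale = res$scale,
        valid = valid, temperature_C = temp)
    }
  }
  all <- do.call(rbind, rows)
  structure(list(
    trajectories = all[, c("frame_index", "roi", "label", "x", "y",
                           "score", "scale", "valid")],
    readings = all[, c("frame_index", "roi", "label", "temperature_C",
                       "valid")]),
    class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  tr <- x$trajectories
  cat(sprintf("<tracking_result> %d frames x %d ROIs, %.1f%% valid\n",
              length(unique(tr$frame_index)), length(unique(tr$roi)),
              100 * mean(tr$valid)))
  invisible(x)
}

#' Expected ROI top-left positions from generator ground truth
#'
#' Converts the per-region blob-center ground truth emitted by
#' [generate_sequence()] into per-ROI expected top-left positions, by
#' applying each frame's true translation offsets to the ROI's reference
#' position (matching ROIs to regions by label).
#'
#' @param rois List of `roi_profile`s.
#' @param truth Ground-truth data frame from [generate_sequence()].
#' @return Data frame with columns `frame_index`, `roi`, `label`, `x`, `y`,
#'   `occluded`.
#' @export
roi_truth <- function(rois, truth) {
  out <- lapply(rois, function(r) {
    tr <- truth[truth$label == r$label, ]
    if (nrow(tr) == 0L)
      stop(sprintf("no ground truth for region label '%s'", r$label),
           call. = FALSE)
    data.frame(frame_index = tr$frame_index, roi = r$roi, label = r$label,
               x = r$x + tr$dx, y = r$y + tr$dy, occluded = tr$occluded)
  })
  do.call(rbind, out)
}
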