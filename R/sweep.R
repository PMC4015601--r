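#' Rotation-tolerance sweep on a synthetic phantom
#'
#' Measures how far a matcher can be rotated away from its reference
#' template before localization fails, without ever re-extracting the
#' template. A single 2:1 anisotropic Gaussian blob (peak 36.5 degrees C on
#' a 34 degrees C background, sensor noise sigma 0.05 degrees C) is rendered
#' on a square frame; a template is extracted at angle 0 and centered on the
#' blob; then the blob is rotated about the ROI center in steps, and at each
#' angle the matcher searches a window around the reference position. The
#' localization error is the Euclidean distance between the found and true
#' top-left positions (the true position never moves, since rotation is
#' about the ROI center).
#'
#' @param matcher `"rpt"`, `"ncc"` or `"parametric"`.
#' @param angles Rotation angles to sweep, degrees (default 0-30 in
#'   1-degree steps).
#' @param frame_size Square frame side, pixels (default 256).
#' @param template_size Square template side, pixels (default 32).
#' @param window Search half-width, pixels (default 12).
#' @param noise_sigma Sensor noise, degrees C (default 0.05); fresh noise is
#'   drawn at each angle.
#' @param seed Base RNG seed.
#'
#' @return Data frame with columns `angle`, `x`, `y`, `score`, `error_px`.
#'   Use [rotation_tolerance()] to reduce it to a single tolerance angle.
#' @export
rotation_sweep <- function(matcher = c("rpt", "ncc", "parametric"),
                           angles = 0:30, frame_size = 256L,
                           template_size = 32L, window = 12L,
                           noise_sigma = 0.05, seed = 1L) {
  matcher <- match.arg(matcher)
  ctr <- (frame_size + 1) / 2
  spec <- phantom_spec(
    frame_size = c(frame_size, frame_size), background = 34,
    regions = list(phantom_region("facial", center = c(ctr, ctr),
                                  sigma = c(template_size / 4,
                                            template_size / 8),
                                  peak = 36.5)),
    noise_sigma = noise_sigma, seed = seed)
  x0 <- as.integer(round(ctr - template_size / 2 + 0.5))
  y0 <- x0
  frame0 <- render_frame(spec, seed = seed)
  rois <- define_rois(frame0,
                      data.frame(label = "facial", x = x0, y = y0,
                                 height = template_size, width = template_size),
                      run_config(matcher = matcher))
  out <- lapply(seq_along(angles), function(i) {
    fr <- render_frame(spec, pose = list(rotate = angles[i]),
                       seed = seed + 97L * i)
    res <- search_frame(fr, rois[[1]], position = c(x0, y0), window = window)
    data.frame(angle = angles[i], x = res$x, y = res$y, score = res$score,
               error_px = sqrt((res$x - x0)^2 + (res$y - y0)^2))
  })
  do.call(rbind, out)
}

#' Largest tolerated rotation angle from a sweep
#'
#' Reduces a [rotation_sweep()] result to the largest swept angle at which
#' the localization error is within tolerance. With `contiguous = TRUE` the
#' stricter reduction is used instead: the largest angle up to which the
#' error stays within tolerance at every step. The two differ when
#' localization jitter is noise-driven rather than rotation-driven (on the
#' standard phantom the ring-projection matcher's error does not grow with
#' angle at all; isolated failures are sensor-noise outliers).
#'
#' @param sweep Data frame from [rotation_sweep()].
#' @param tolerance_px Maximum localization error in pixels (default 2).
#' @param contiguous Require every smaller angle to pass too
#'   (default `FALSE`).
#' @return The largest tolerated angle in degrees (`NA` if no angle
#'   passes).
#' @export
rotation_tolerance <- function(sweep, tolerance_px = 2, contiguous = FALSE) {
  sweep <- sweep[order(sweep$angle), ]
  ok <- sweep$error_px <= tolerance_px
  if (!any(ok)) return(NA_real_)
  if (!contiguous) return(max(sweep$angle[ok]))
  bad <- which(!ok)
  if (length(bad) == 0L) return(max(sweep$angle))
  if (bad[1] == 1L) return(NA_real_)
  sweep$angle[bad[1] - 1L]
}

#' Scale-recovery trials for the parametric matcher
#'
#' Repeatedly renders the standard single-blob phantom at a random true
#' scale, matches the (unchanged) reference window against a parametric
#' template built from the base scale grid, and records the estimated scale
#' `s_q` next to the truth. Summarize with `median(abs(s_q - s_true))`.
#'
#' @param n_trials Number of trials (default 50).
#' @param scale_range True scale drawn uniformly from this range
#'   (default 0.85-1.45).
#' @param base_scales Scale grid of the parametric template
#'   (default 0.8, 1.0, 1.2, 1.4, 1.6).
#' @param frame_size,template_size,noise_sigma As in [rotation_sweep()]
#'   (default frame 128 px here; the blob never leaves it).
#' @param seed Base RNG seed.
#' @return Data frame with columns `trial`, `s_true`, `s_q`, `score`.
#' @export
scale_recovery_trials <- function(n_trials = 50L,
                                  scale_range = c(0.85, 1.45),
                                  base_scales = c(0.8, 1.0, 1.2, 1.4, 1.6),
                                  frame_size = 128L, template_size = 32L,
                                  noise_sigma = 0.05, seed = 1L) {
  ctr <- (frame_size + 1) / 2
  spec <- phantom_spec(
    frame_size = c(frame_size, frame_size), background = 34,
    regions = list(phantom_region("facial", center = c(ctr, ctr),
                                  sigma = c(template_size / 4,
                                            template_size / 8),
                                  peak = 36.5)),
    noise_sigma = noise_sigma, seed = seed)
  x0 <- as.integer(round(ctr - template_size / 2 + 0.5))
  frame0 <- render_frame(spec, seed = seed)
  template <- frame0$values[x0:(x0 + template_size - 1L),
                            x0:(x0 + template_size - 1L)]
  pt <- parametric_template(template, base_scales)
  lut <- build_ring_lut(template_size, template_size)
  s_true <- with_seed(seed, runif(n_trials, scale_range[1], scale_range[2]))
  out <- lapply(seq_len(n_trials), function(t) {
    fr <- render_frame(spec, pose = list(scale = s_true[t]),
                       seed = seed + 131L * t)
    scene <- fr$values[x0:(x0 + template_size - 1L),
                       x0:(x0 + template_size - 1L)]
    m <- match_parametric(pt, ring_project(scene, lut))
    data.frame(trial = t, s_true = s_true[t], s_q = m$scale, score = m$score)
  })
  do.call(rbind, out)
}
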