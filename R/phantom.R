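# run expr with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Define one warm body region of a phantom
#'
#' A region is an anisotropic Gaussian warm blob: smooth like a real skin
#' thermogram, but with a distinct major axis so that in-plane rotation is
#' observable. `sigma` gives the standard deviations along the major and
#' minor axes in pixels; `theta` is the major-axis orientation in degrees
#' (positive rotates from +x toward +y, i.e. clockwise on screen).
#'
#' @param label Anatomical-region name (e.g. "facial", "abdominal",
#'   "upper-limb", "lower-limb", "incubator-reference").
#' @param center Blob center `(x, y)` in pixels (1-based, x = column).
#' @param sigma Axis standard deviations `(major, minor)` in pixels.
#' @param peak Peak temperature at the blob center, degrees C.
#' @param theta Major-axis orientation, degrees.
#' @return A list describing the region.
#' @export
phantom_region <- function(label, center, sigma, peak, theta = 0) {
  stopifnot(length(center) == 2L, length(sigma) == 2L, all(sigma > 0))
  list(label = as.character(label), center = as.numeric(center),
       sigma = as.numeric(sigma), peak = as.numeric(peak),
       theta = as.numeric(theta))
}

#' Specify a synthetic thermal phantom
#'
#' Describes a warm, anisotropic body on a cooler uniform background — a
#' stand-in for a neonate imaged inside an incubator. Defaults follow
#' clinically plausible values: background 34 degrees C (incubator air), a
#' facial blob peaking at 36.5 degrees C with a 2:1 axis ratio, and i.i.d.
#' Gaussian sensor noise with sigma 0.05 degrees C.
#'
#' At least one region must be anisotropic (axis ratio >= 1.5) so that
#' in-plane rotation has an observable effect; all peaks must exceed the
#' background temperature.
#'
#' @param frame_size Frame dimensions `(rows, cols)` in pixels.
#' @param background Background temperature, degrees C.
#' @param regions List of [phantom_region()] blobs.
#' @param noise_sigma Per-pixel Gaussian noise standard deviation, degrees C.
#' @param seed Integer seed making every render reproducible.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec()
#' fr <- render_frame(spec)
#' @export
phantom_spec <- function(frame_size = c(256L, 256L),
                         background = 34,
                         regions = list(
                           phantom_region("facial", center = c(128, 128),
                                          sigma = c(8, 4), peak = 36.5)),
                         noise_sigma = 0.05,
                         seed = 1L) {
  stopifnot(length(frame_size) == 2L, all(frame_size >= 2))
  if (length(regions) == 0L)
    stop("at least one region is required", call. = FALSE)
  peaks <- vapply(regions, `[[`, numeric(1), "peak")
  if (any(peaks <= background))
    stop("all region peak temperatures must exceed the background", call. = FALSE)
  ratios <- vapply(regions, function(r) max(r$sigma) / min(r$sigma), numeric(1))
  if (all(ratios < 1.5))
    stop("at least one region must be anisotropic (axis ratio >= 1.5)",
         call. = FALSE)
  if (noise_sigma < 0)
    stop("`noise_sigma` must be non-negative", call. = FALSE)
  structure(list(frame_size = as.integer(frame_size),
                 background = as.numeric(background),
                 regions = regions,
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Render one phantom frame at a given pose
#'
#' Evaluates every (non-occluded) Gaussian blob analytically at the posed
#' location: the blob center is shifted by `translate`, and the blob is
#' rotated by `rotate` degrees and scaled by `scale` about its own center
#' (scaling multiplies the axis sigmas). Zero-mean Gaussian sensor noise
#' from the seeded generator is added on top. Occluded regions are simply
#' omitted, i.e. replaced by background (plus noise).
#'
#' @param spec A [phantom_spec()].
#' @param pose List with `translate` (`c(dx, dy)` pixels), `rotate`
#'   (degrees) and `scale`; missing entries default to the identity pose.
#' @param seed RNG seed for the noise (default `spec$seed`).
#' @param occluded Character vector of region labels to occlude, or `TRUE`
#'   for all.
#' @param frame_index,timestamp Metadata for the returned frame.
#' @return A [thermal_frame()].
#' @export
render_frame <- function(spec, pose = list(), seed = spec$seed,
                         occluded = character(), frame_index = 0L,
                         timestamp = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  translate <- if (is.null(pose$translate)) c(0, 0) else pose$translate
  rotate <- if (is.null(pose$rotate)) 0 else pose$rotate
  scale <- if (is.null(pose$scale)) 1 else pose$scale
  if (!all(is.finite(c(translate, rotate, scale))) || scale <= 0)
    stop("pose must be finite with positive scale", call. = FALSE)
  H <- spec$frame_size[1]; W <- spec$frame_size[2]
  vals <- matrix(spec$background, H, W)
  xg <- matrix(seq_len(W), H, W, byrow = TRUE)
  yg <- matrix(seq_len(H), H, W)
  occ_all <- isTRUE(occluded)
  for (reg in spec$regions) {
    if (occ_all || reg$label %in% occluded) next
    cx <- reg$center[1] + translate[1]
    cy <- reg$center[2] + translate[2]
    ang <- (reg$theta + rotate) * pi / 180
    dx <- xg - cx; dy <- yg - cy
    u1 <- (cos(ang) * dx + sin(ang) * dy) / scale
    u2 <- (-sin(ang) * dx + cos(ang) * dy) / scale
    vals <- vals + (reg$peak - spec$background) *
      exp(-0.5 * ((u1 / reg$sigma[1])^2 + (u2 / reg$sigma[2])^2))
  }
  if (spec$noise_sigma > 0)
    vals <- vals + with_seed(seed,
      matrix(rnorm(H * W, 0, spec$noise_sigma), H, W))
  thermal_frame(vals, timestamp = timestamp, frame_index = frame_index,
                plausible_range = NULL)
}

#' Build a per-frame motion script
#'
#' The script holds, for each frame, the absolute pose offsets relative to
#' frame 0: translation `(dx, dy)` in pixels, in-plane rotation in degrees,
#' and scale factor. Scalars are recycled across frames. Occlusion
#' intervals are inclusive `(start, end)` pairs of frame indices during
#' which every region is replaced by background.
#'
#' @param n_frames Number of frames.
#' @param dx,dy Per-frame translation offsets (length 1 or `n_frames`).
#' @param rotate Per-frame rotation, degrees.
#' @param scale Per-frame scale factor.
#' @param occlusions List of `c(start, end)` frame-index pairs (0-based,
#'   inclusive).
#' @return A data frame of class `motion_script` with columns
#'   `frame_index`, `dx`, `dy`, `rotate`, `scale` and attribute
#'   `occlusions`.
#' @examples
#' sc <- motion_script(50, dx = 0:49, dy = 0)  # 1 px/frame drift
#' @export
motion_script <- function(n_frames, dx = 0, dy = 0, rotate = 0, scale = 1,
                          occlusions = list()) {
  n_frames <- as.integer(n_frames)
  stopifnot(n_frames >= 1L)
  rec <- function(v, nm) {
    if (length(v) == 1L) v <- rep(v, n_frames)
    if (length(v) != n_frames)
      stop(sprintf("`%s` must have length 1 or n_frames = %d", nm, n_frames),
           call. = FALSE)
    as.numeric(v)
  }
  for (occ in occlusions)
    if (length(occ) != 2L || occ[1] > occ[2] || occ[1] < 0 || occ[2] >= n_frames)
      stop("occlusion intervals must be c(start, end) within 0..n_frames-1",
           call. = FALSE)
  out <- data.frame(frame_index = 0:(n_frames - 1L),
                    dx = rec(dx, "dx"), dy = rec(dy, "dy"),
                    rotate = rec(rotate, "rotate"), scale = rec(scale, "scale"))
  attr(out, "occlusions") <- occlusions
  class(out) <- c("motion_script", class(out))
  out
}

occluded_at <- function(script, frame_index) {
  any(vapply(attr(script, "occlusions"), function(occ)
    frame_index >= occ[1] && frame_index <= occ[2], logical(1)))
}

#' Generate a synthetic thermal sequence with ground truth
#'
#' Renders each frame of a [motion_script()] applied to a [phantom_spec()]
#' and records the true per-region blob centers frame by frame. Frame `f`
#' uses noise seed `spec$seed + f`, so the whole sequence is reproducible
#' while frames stay mutually independent.
#'
#' @param spec A [phantom_spec()].
#' @param script A [motion_script()].
#' @param frame_rate Frames per second (default 25).
#' @return List with `sequence` (a [thermal_sequence()]) and `truth` (data
#'   frame with columns `frame_index`, `label`, `x`, `y`, `dx`, `dy`,
#'   `occluded` — `x`, `y` are the true blob centers).
#' @export
generate_sequence <- function(spec, script, frame_rate = 25) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(script, "motion_script"))
  n <- nrow(script)
  frames <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    row <- script[i, ]
    occ <- occluded_at(script, row$frame_index)
    frames[[i]] <- render_frame(
      spec,
      pose = list(translate = c(row$dx, row$dy), rotate = row$rotate,
                  scale = row$scale),
      seed = spec$seed + row$frame_index,
      occluded = if (occ) TRUE else character(),
      frame_index = row$frame_index,
      timestamp = row$frame_index / frame_rate)
    truth[[i]] <- data.frame(
      frame_index = row$frame_index,
      label = vapply(spec$regions, `[[`, character(1), "label"),
      x = vapply(spec$regions, function(r) r$center[1], numeric(1)) + row$dx,
      y = vapply(spec$regions, function(r) r$center[2], numeric(1)) + row$dy,
      dx = row$dx, dy = row$dy, occluded = occ)
  }
  list(sequence = thermal_sequence(frames, frame_rate = frame_rate),
       truth = do.call(rbind, truth))
}
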