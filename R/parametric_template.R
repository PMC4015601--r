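#' Build a base ring-projection set from a template at several scales
#'
#' Rescales the template image by each scale factor (bilinear interpolation),
#' ring-projects every rescaled version, and truncates all signatures to a
#' common maximum radius so they are directly comparable. The resulting base
#' set spans the range of apparent object sizes the matcher should tolerate.
#'
#' @param template Numeric matrix (the reference ROI) or [thermal_frame()].
#' @param scales Strictly increasing positive scale factors; must include
#'   values bracketing the scene scales you expect.
#' @param common_R Common maximum ring radius. Default: the largest radius
#'   admitted by the smallest rescaled template.
#'
#' @return An object of class `base_ring_set`: list with `vectors` (a
#'   `(common_R + 1) x length(scales)` matrix, one ring signature per
#'   column), `scales`, and `R`.
#' @export
build_base_set <- function(template, scales = c(0.8, 0.9, 1.0, 1.1, 1.2),
                           common_R = NULL) {
  values <- if (inherits(template, "thermal_frame")) template$values else template
  stopifnot(is.matrix(values))
  if (length(scales) < 1L || any(!is.finite(scales)) || any(scales <= 0))
    stop("`scales` must be positive and finite", call. = FALSE)
  if (is.unsorted(scales, strictly = TRUE))
    stop("`scales` must be strictly increasing", call. = FALSE)
  scaled <- lapply(scales, function(s) {
    if (abs(s - 1) < 1e-12) return(values)
    w <- max(3L, as.integer(round(nrow(values) * s)))
    h <- max(3L, as.integer(round(ncol(values) * s)))
    as.matrix(EBImage::resize(values, w = w, h = h))
  })
  max_R <- vapply(scaled, function(m) min(dim(m)) %/% 2L, integer(1))
  if (is.null(common_R)) common_R <- min(max_R)
  common_R <- as.integer(common_R)
  too_small <- which(max_R < common_R)
  if (length(too_small) > 0L)
    stop(sprintf(
      "scaled template at scale %g is smaller than 2*common_R+1 = %d px",
      scales[too_small[1]], 2L * common_R + 1L), call. = FALSE)
  vectors <- vapply(scaled, function(m) {
    lut <- build_ring_lut(nrow(m), ncol(m))
    ring_project(m, lut)[seq_len(common_R + 1L)]
  }, numeric(common_R + 1L))
  vectors <- matrix(vectors, nrow = common_R + 1L)
  structure(list(vectors = vectors, scales = as.numeric(scales), R = common_R),
            class = "base_ring_set")
}

#' Build a parametric (multi-scale) template
#'
#' Combines a [build_base_set()] with its Gram matrix `L` of pairwise
#' normalized correlations (diagonal 100). `L` is fixed at training time;
#' at match time only the correlation vector `F` between the scene signature
#' and the base set is computed, and the mixing weights follow from a
#' closed-form Lagrange-multiplier solve — no iteration is involved.
#'
#' @inheritParams build_base_set
#' @return An object of class `parametric_template`: list with `base`
#'   (the [build_base_set()]) and `L` (the Gram matrix).
#' @export
parametric_template <- function(template, scales = c(0.8, 0.9, 1.0, 1.1, 1.2),
                                common_R = NULL) {
  base <- build_base_set(template, scales, common_R)
  n <- ncol(base$vectors)
  L <- matrix(100, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      L[i, j] <- L[j, i] <-
        normalized_correlation(base$vectors[, i], base$vectors[, j])
    }
  }
  structure(list(base = base, L = L), class = "parametric_template")
}

#' @export
print.parametric_template <- function(x, ...) {
  cat(sprintf("<parametric_template> %d scales (%s), R = %d\n",
              length(x$base$scales),
              paste(format(x$base$scales), collapse = ", "), x$base$R))
  invisible(x)
}

#' Solve for parametric-template mixing weights
#'
#' Closed-form Lagrange-multiplier solution of the sum-to-one constrained
#' correlation maximization: `w = L^-1 F / (1' L^-1 F)`, which satisfies
#' `sum(w) = 1` exactly. The closed form does not enforce the box constraint
#' `0 <= w_i <= 1`; when components fall outside it, the solve is projected
#' onto the simplex by active-set restriction: negative components are fixed
#' at zero and the same closed form is re-solved on the remaining support
#' until the solution is feasible (at most `n` restrictions, each a direct
#' linear solve — no gradient iteration, no initialization, fully
#' deterministic). Whether projection was triggered is recorded in the
#' `"projected"` attribute. A small ridge (`1e-6 * trace(L)/n`) is added
#' when `L` is ill-conditioned (condition number above 1e10).
#'
#' @param L Symmetric Gram matrix of pairwise NC values between base
#'   signatures (diagonal 100).
#' @param F_vec Vector of NC values between the scene signature and each
#'   base signature.
#'
#' @return Weight vector summing to 1, all components in `[0, 1]`, with
#'   attribute `projected` (logical: was the simplex projection triggered).
#' @export
solve_weights <- function(L, F_vec) {
  stopifnot(is.matrix(L), nrow(L) == ncol(L), length(F_vec) == nrow(L))
  n <- nrow(L)
  if (n == 1L)
    return(structure(1, projected = FALSE))
  kap <- tryCatch(kappa(L, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kap) || kap > 1e10)
    L <- L + diag(1e-6 * sum(diag(L)) / n, n)
  active <- seq_len(n)
  projected <- FALSE
  for (round in seq_len(n)) {
    raw <- tryCatch(solve(L[active, active, drop = FALSE], F_vec[active]),
                    error = function(e)
                      stop("numerical error: singular Gram matrix after regularization",
                           call. = FALSE))
    denom <- sum(raw)
    if (abs(denom) < 1e-12 * max(sum(abs(raw)), 1))
      stop("degenerate-solution error: weights sum to zero", call. = FALSE)
    w <- raw / denom
    if (all(w >= -1e-12)) {
      out <- numeric(n)
      out[active] <- pmax(w, 0)
      out <- out / sum(out)
      return(structure(out, projected = projected))
    }
    projected <- TRUE
    active <- active[w > 0]
    if (length(active) == 0L)
      stop("degenerate-solution error: no non-negative weight mass",
           call. = FALSE)
    if (length(active) == 1L) {
      out <- numeric(n)
      out[active] <- 1
      return(structure(out, projected = TRUE))
    }
  }
  out <- numeric(n)
  out[active] <- 1 / length(active)
  structure(out, projected = TRUE)
}

#' Estimate scene scale from parametric weights
#'
#' The scale estimate is the weight-averaged base scale,
#' `s_q = sum(w_i * s_i)`.
#'
#' @param weights Weight vector summing to 1.
#' @param scales Base scale factors, same length.
#' @return The estimated scale factor (scalar).
#' @export
estimate_scale <- function(weights, scales) {
  if (length(weights) != length(scales))
    stop(sprintf("length mismatch: %d weights vs %d scales",
                 length(weights), length(scales)), call. = FALSE)
  sum(weights * scales)
}

#' Match a scene signature against a parametric template
#'
#' Computes the correlation vector `F` between the scene ring signature and
#' every base signature, solves for the mixing weights, forms the normalized
#' weighted parametric vector, and returns its NC with the scene together
#' with the scale estimate. A scene signature longer than the base radius is
#' truncated to the common length (the extra outer rings carry no matching
#' information for the base set).
#'
#' @param pt A [parametric_template()].
#' @param scene_vector Ring signature of the scene sub-image, length
#'   `>= R + 1`.
#'
#' @return List with `score` (NC units), `scale` (the `s_q` estimate),
#'   `weights`, and `F` (the correlation vector).
#' @export
match_parametric <- function(pt, scene_vector) {
  stopifnot(inherits(pt, "parametric_template"))
  len <- pt$base$R + 1L
  if (length(scene_vector) < len)
    stop(sprintf("scene vector too short: %d < %d", length(scene_vector), len),
         call. = FALSE)
  scene <- scene_vector[seq_len(len)]
  F_vec <- apply(pt$base$vectors, 2L, normalized_correlation, b = scene)
  w <- solve_weights(pt$L, F_vec)
  ptp <- as.vector(pt$base$vectors %*% w)
  nrm <- sqrt(sum(ptp^2))
  if (nrm > 0) ptp <- ptp / nrm
  list(score = normalized_correlation(ptp, scene),
       scale = estimate_scale(w, pt$base$scales),
       weights = w, F = F_vec)
}
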