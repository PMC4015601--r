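#' Build a ring look-up table for a template size
#'
#' Assigns every pixel of an `M x N` template its integer ring radius
#' `r = floor(sqrt((row - rc)^2 + (col - cc)^2))` from the template center
#' `(rc, cc) = ((M + 1)/2, (N + 1)/2)` (half-integer for even sides; radii
#' are computed in floating point before flooring). The maximum usable
#' radius is `R = floor(min(M, N) / 2)`, the largest ring that lies fully
#' inside the template; pixels beyond `R` are excluded from all projections.
#'
#' The LUT also carries a dense `(R + 1) x (M * N)` averaging operator so
#' that many candidate sub-images can be ring-projected with one matrix
#' product during tracking.
#'
#' @param M Template height (rows), `>= 3`.
#' @param N Template width (cols), `>= 3`.
#'
#' @return An object of class `ring_lut`: list with `radius` (M x N integer
#'   matrix, `NA` beyond `R`), `counts` (pixels per ring, `S_r`, r = 0..R),
#'   `R`, `M`, `N`, `inside` (logical matrix), and `proj` (the averaging
#'   operator).
#' @examples
#' lut <- build_ring_lut(5, 5)
#' lut$counts  # 1 8 16
#' @export
build_ring_lut <- function(M, N) {
  M <- as.integer(M); N <- as.integer(N)
  if (is.na(M) || is.na(N) || M < 3L || N < 3L)
    stop("template must be at least 3x3", call. = FALSE)
  rc <- (M + 1) / 2
  cc <- (N + 1) / 2
  dr <- (seq_len(M) - rc)^2
  dc <- (seq_len(N) - cc)^2
  rad <- floor(sqrt(outer(dr, dc, `+`)))
  R <- min(M, N) %/% 2L
  inside <- rad <= R
  radius <- ifelse(inside, rad, NA_integer_)
  counts <- tabulate(radius[inside] + 1L, nbins = R + 1L)
  if (any(counts == 0L))  # cannot happen for M, N >= 3, kept as a guard
    stop("empty ring in LUT", call. = FALSE)
  proj <- matrix(0, nrow = R + 1L, ncol = M * N)
  idx <- which(inside)
  proj[cbind(radius[idx] + 1L, idx)] <- 1 / counts[radius[idx] + 1L]
  structure(list(radius = radius, counts = counts, R = R, M = M, N = N,
                 inside = inside, proj = proj),
            class = "ring_lut")
}

#' @export
print.ring_lut <- function(x, ...) {
  cat(sprintf("<ring_lut> %d x %d template, R = %d, %d pixels in rings\n",
              x$M, x$N, x$R, sum(x$counts)))
  invisible(x)
}

#' Ring projection transform of a template
#'
#' Reduces a 2-D template to its 1-D rotation-invariant signature: the
#' vector `P(r)`, r = 0..R, of mean pixel intensities over the concentric
#' integer-radius rings defined by the LUT. Rotating the template about its
#' center permutes pixels within rings (up to resampling), so the signature
#' is unchanged by in-plane rotation.
#'
#' @param template Numeric matrix (or [thermal_frame()]) matching the LUT
#'   dimensions.
#' @param lut A [build_ring_lut()] result for the same `M x N`.
#'
#' @return Numeric vector of length `R + 1`.
#' @export
ring_project <- function(template, lut) {
  values <- if (inherits(template, "thermal_frame")) template$values else template
  stopifnot(inherits(lut, "ring_lut"))
  if (!is.matrix(values) || nrow(values) != lut$M || ncol(values) != lut$N)
    stop(sprintf("template dimensions must match LUT (%d x %d)", lut$M, lut$N),
         call. = FALSE)
  as.vector(lut$proj %*% as.vector(values))
}

#' Normalized correlation between two ring-projection vectors
#'
#' Pearson-type normalized correlation scaled to `[-100, 100]`. The score is
#' invariant to gain and offset in either vector (`NC(v, a*v + b) = 100` for
#' `a > 0`), which is what makes the match robust to global changes in
#' thermal contrast. Undefined (error) when either vector has zero variance.
#'
#' @param a,b Numeric vectors of equal length (at least 2).
#'
#' @return A single score in `[-100, 100]`.
#' @examples
#' normalized_correlation(c(1, 2, 3), c(2, 4, 6))  # 100
#' @export
normalized_correlation <- function(a, b) {
  if (length(a) != length(b))
    stop(sprintf("length mismatch: %d vs %d", length(a), length(b)),
         call. = FALSE)
  n <- length(a)
  if (n < 2L)
    stop("vectors must have length >= 2", call. = FALSE)
  da <- n * sum(a^2) - sum(a)^2
  db <- n * sum(b^2) - sum(b)^2
  tol_a <- 1e-12 * n * max(sum(a^2), 1)
  tol_b <- 1e-12 * n * max(sum(b^2), 1)
  if (da <= tol_a || db <= tol_b)
    stop("undefined correlation: constant (zero-variance) vector", call. = FALSE)
  100 * (n * sum(a * b) - sum(a) * sum(b)) / sqrt(da * db)
}

# Vectorized NC of one reference vector against each column of a matrix.
# Columns with (near-)zero variance score NA. Internal hot path for search.
nc_columns <- function(ref, mat) {
  n <- length(ref)
  stopifnot(nrow(mat) == n)
  sr <- sum(ref)
  dr <- n * sum(ref^2) - sr^2
  cs <- colSums(mat)
  dm <- n * colSums(mat^2) - cs^2
  num <- n * as.vector(crossprod(mat, ref)) - cs * sr
  den <- sqrt(pmax(dr, 0) * pmax(dm, 0))
  bad <- dm <= 1e-12 * n * pmax(colSums(mat^2), 1)
  out <- ifelse(bad | den == 0, NA_real_, 100 * num / den)
  out
}

#' Mean intensity of a template
#'
#' Arithmetic mean over all pixels of the rectangular template. When the
#' ring set covers every pixel this equals the ring-count-weighted mean of
#' the ring projection vector, `sum(S_r * P(r)) / sum(S_r)`.
#'
#' @param template Numeric matrix or [thermal_frame()].
#' @return Mean intensity (scalar).
#' @export
template_mean <- function(template) {
  values <- if (inherits(template, "thermal_frame")) template$values else template
  if (length(values) == 0L)
    stop("empty template", call. = FALSE)
  mean(values)
}
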