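# shared fixtures and independent oracles, all built in code

# single-blob phantom with the standard clinical-plausible values
test_spec <- function(frame_size = 64L, center = NULL, sigma = c(8, 4),
                      peak = 36.5, noise_sigma = 0.05, seed = 1L) {
  if (is.null(center)) center <- rep((frame_size + 1) / 2, 2)
  phantom_spec(frame_size = c(frame_size, frame_size), background = 34,
               regions = list(phantom_region("facial", center = center,
                                             sigma = sigma, peak = peak)),
               noise_sigma = noise_sigma, seed = seed)
}

# smooth isotropic radial Gaussian template (analytic, used where a template
# with known radial profile is needed)
radial_template <- function(n, sig = n / 5, bg = 34, peak = 36.5) {
  c0 <- (n + 1) / 2
  d2 <- outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, `+`)
  bg + (peak - bg) * exp(-d2 / (2 * sig^2))
}

# exhaustive per-ring-mean oracle: explicit double loop, same binning rule
# as the spec of the transform (floor of Euclidean radius, R = min(M,N)/2)
ring_oracle <- function(values) {
  M <- nrow(values); N <- ncol(values)
  rc <- (M + 1) / 2; cc <- (N + 1) / 2
  R <- min(M, N) %/% 2L
  sums <- numeric(R + 1); counts <- integer(R + 1)
  for (i in seq_len(M)) for (j in seq_len(N)) {
    r <- floor(sqrt((i - rc)^2 + (j - cc)^2))
    if (r <= R) {
      sums[r + 1] <- sums[r + 1] + values[i, j]
      counts[r + 1] <- counts[r + 1] + 1L
    }
  }
  list(p = sums / counts, counts = counts)
}

# all weight vectors on the simplex with given step (compositions of 1/step)
simplex_grid <- function(n_parts, step = 0.05) {
  total <- round(1 / step)
  comps <- function(total, parts) {
    if (parts == 1L) return(matrix(total, 1, 1))
    do.call(rbind, lapply(0:total, function(k)
      cbind(k, comps(total - k, parts - 1L))))
  }
  comps(total, n_parts) * step
}

# Eq-7-style objective for a weight vector given Gram matrix and F vector
# (numerator/denominator form of the normalized correlation of the weighted
# combination, valid when L and F are inner products of centered unit
# vectors; used only as a comparative objective)
lm_objective <- function(w, L, F_vec) {
  q <- as.numeric(t(w) %*% L %*% w)
  if (q <= 0) return(-Inf)
  sum(w * F_vec) / sqrt(q)
}

# grid-search oracle: maximize actual NC of the weighted combination
grid_search_match <- function(vectors, scene, step = 0.05) {
  G <- simplex_grid(ncol(vectors), step)
  obj <- apply(G, 1L, function(w) {
    v <- as.vector(vectors %*% w)
    if (sd(v) == 0) return(-Inf)
    normalized_correlation(v, scene)
  })
  k <- which.max(obj)
  list(weights = G[k, ], score = obj[k])
}

rotate90 <- function(m) t(m[nrow(m):1, , drop = FALSE])

# independent radiance-balance root-finding oracle for the correction
correction_oracle <- function(apparent, eps, tau, t_amb, t_foil,
                              eps_reg = 1) {
  W <- function(t) (t + 273.15)^4
  w_meas <- eps_reg * W(apparent) + (1 - eps_reg) * W(t_amb)
  f <- function(t) tau * eps * W(t) + tau * (1 - eps) * W(t_amb) +
    (1 - tau) * W(t_foil) - w_meas
  uniroot(f, c(-100, 300), tol = 1e-10)$root
}
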