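# shared fixtures: small orders keep unit tests fast; the 11 x 13 system
# order (143) is exercised where a check is specific to it

S15 <- twin_prime_smatrix(3, 5)
S35 <- twin_prime_smatrix(5, 7)
S143 <- twin_prime_smatrix(11, 13)

# (3, 5)'s diagonal scan cycles after 5 steps, so order 35 is the small
# workhorse wherever longer or full diagonal scans are needed
scheme15 <- function(m = 5, ...) coding_scheme(3, 5, m, ...)
scheme35 <- function(m = 35, ...) coding_scheme(5, 7, m, ...)
scheme143 <- function(m = 91, ...) coding_scheme(11, 13, m, ...)

# independent bucket-signal oracle: naive double loop over Eq. y_u = S[u,] . x
naive_bucket <- function(S, scene, rows) {
  x <- as.vector(t(if (inherits(scene, "thermal_scene")) scene$radiance
                   else scene))
  vapply(rows, function(u) {
    acc <- 0
    for (v in 0:(S$n - 1L)) acc <- acc + S$matrix[u + 1L, v + 1L] * x[v + 1L]
    acc
  }, numeric(1))
}

# independent torus-distance oracle: exhaustive search over measured sites
brute_min_dist <- function(u, measured, p, q, metric) {
  ui <- u %/% q; uj <- u %% q
  best <- Inf
  for (m0 in measured) {
    di <- abs(ui - m0 %/% q); di <- min(di, p - di)
    dj <- abs(uj - m0 %% q); dj <- min(dj, q - dj)
    d <- switch(metric, chebyshev = max(di, dj),
                euclidean = sqrt(di^2 + dj^2), manhattan = di + dj)
    best <- min(best, d)
  }
  best
}

# a smooth random scene: low-frequency cosine ridge plus a Gaussian blob
random_smooth_scene <- function(p, q) {
  rr <- matrix(seq_len(p) - 0.5, p, q)
  cc <- matrix(rep(seq_len(q) - 0.5, each = p), p, q)
  ctr <- c(stats::runif(1, 1, p - 1), stats::runif(1, 1, q - 1))
  blob <- exp(-((rr - ctr[1])^2 + (cc - ctr[2])^2) / (2 * stats::runif(1, 1.5, 3)^2))
  wave <- 0.3 * cos(2 * pi * (rr / p + stats::runif(1))) *
    cos(2 * pi * (cc / q + stats::runif(1)))
  thermal_scene(1 + blob + wave)
}

expect_all_equal <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}
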