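#' Thermal scene
#'
#' A ground-truth `p x q` radiance grid, optionally carrying the source
#' temperature grid it was derived from. Radiance is in arbitrary linear
#' detector units; physical meaning enters only through a calibration
#' model (see [fit_calibration()]).
#'
#' @param radiance non-negative numeric `p x q` matrix.
#' @param temperature_K optional `p x q` matrix of source temperatures in
#'   kelvin from which `radiance` was derived.
#' @return An object of class `"thermal_scene"`.
#' @export
thermal_scene <- function(radiance, temperature_K = NULL) {
  radiance <- as.matrix(radiance)
  if (any(!is.finite(radiance)) || any(radiance < 0)) {
    stop("radiance must be finite and non-negative")
  }
  if (!is.null(temperature_K)) {
    temperature_K <- as.matrix(temperature_K)
    stopifnot(identical(dim(temperature_K), dim(radiance)))
  }
  structure(list(radiance = radiance, temperature_K = temperature_K,
                 p = nrow(radiance), q = ncol(radiance)),
            class = "thermal_scene")
}

# row-major flattening of a p x q grid into x_v, v = q*i + j
flatten_scene <- function(scene) {
  g <- if (inherits(scene, "thermal_scene")) scene$radiance else as.matrix(scene)
  as.vector(t(g))
}

#' Simulate compressed bucket-signal acquisition
#'
#' Each scan step measures one bucket signal: the inner product of the
#' flattened scene with one row of the S-matrix,
#' `y_u = sum_v S[u, v] * x_v`, scaled by a detector gain and perturbed by
#' additive i.i.d. Gaussian noise. The modulation/lock-in detection chain
#' is modelled as this single scalar gain plus noise; with
#' `noise_sigma = 0` the buckets are exact inner products.
#'
#' @param scene a `"thermal_scene"` (or `p x q` matrix) matching the
#'   scheme's shape.
#' @param S an `"smatrix"`.
#' @param scheme a `"coding_scheme"` consistent with `S` (same `p`, `q`).
#' @param noise_sigma standard deviation of additive Gaussian noise on each
#'   bucket, in detector units (default 0).
#' @param gain scalar detector gain (default 1).
#' @param seed optional integer seed; recorded in the output for replay.
#' @return An object of class `"scan_record"`: list with `measured_rows`
#'   (0-based), `bucket` (length-`m` numeric), `noise_sigma`, `gain`,
#'   `seed`, `p`, `q`, `n`, `m`.
#' @examples
#' S <- twin_prime_smatrix(3, 5)
#' sch <- coding_scheme(3, 5, m = 10)
#' rec <- simulate_scan(matrix(1, 3, 5), S, sch)
#' all(rec$bucket == 8)  # uniform scene: every bucket = row weight
#' @export
simulate_scan <- function(scene, S, scheme, noise_sigma = 0, gain = 1,
                          seed = NULL) {
  stopifnot(inherits(S, "smatrix"), inherits(scheme, "coding_scheme"))
  if (scheme$p != S$p || scheme$q != S$q) {
    stop("scheme (", scheme$p, " x ", scheme$q, ") does not match S (",
         S$p, " x ", S$q, ")")
  }
  x <- flatten_scene(scene)
  if (length(x) != S$n) {
    stop("scene has ", length(x), " pixels, expected n = ", S$n)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  rows <- scheme$measured_rows
  y <- gain * as.numeric(S$matrix[rows + 1L, , drop = FALSE] %*% x)
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    y <- y + stats::rnorm(length(y), 0, noise_sigma)
  }
  structure(list(measured_rows = rows, bucket = y,
                 noise_sigma = noise_sigma, gain = gain, seed = seed,
                 p = S$p, q = S$q, n = S$n, m = scheme$m),
            class = "scan_record")
}

#' Simulate an uncompressed full scan
#'
#' Convenience wrapper: a scan with `m = n`, visiting every measurement
#' row exactly once — in diagonal order when the diagonal is a permutation
#' (every twin-prime pair except (3, 5)), otherwise in natural row order.
#' A noiseless full scan followed by [reconstruct()] recovers the scene
#' exactly.
#'
#' @inheritParams simulate_scan
#' @return A `"scan_record"` with `m = n`.
#' @export
simulate_full_scan <- function(scene, S, noise_sigma = 0, gain = 1,
                               seed = NULL) {
  stopifnot(inherits(S, "smatrix"))
  scan <- if (gcd_int((S$q + 1L) %% S$n, S$n) == 1L) "diagonal" else "linear"
  scheme <- coding_scheme(S$p, S$q, m = S$n, scan = scan)
  simulate_scan(scene, S, scheme, noise_sigma = noise_sigma, gain = gain,
                seed = seed)
}
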