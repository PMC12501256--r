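torus_delta <- function(a, b, n) {
  d <- abs(a - b)
  pmin(d, n - d)
}

#' Sampling-uniformity report: distance from unsampled to sampled sites
#'
#' The bucket signals live on a `p x q` grid (row-major reshape of the
#' linear measurement index). For every unsampled site this computes the
#' distance to its nearest sampled neighbor on the torus (indices wrap in
#' both directions, matching the modular neighbor structure of the
#' interpolation), and summarizes the distribution. Small maxima mean the
#' measured signals tile the grid uniformly, which is what makes harmonic
#' interpolation of the gaps accurate.
#'
#' @param measured_rows 0-based linear indices of sampled sites.
#' @param p,q grid shape (`n = p * q`).
#' @param metric one of `"chebyshev"` (default), `"euclidean"`,
#'   `"manhattan"`.
#' @return An object of class `"uniformity_report"`: list with
#'   `distances` (one per unsampled site, empty when `m = n`), `max`,
#'   `mean`, `histogram` (table), `metric`.
#' @export
max_neighbor_distance <- function(measured_rows, p, q,
                                  metric = c("chebyshev", "euclidean",
                                             "manhattan")) {
  metric <- match.arg(metric)
  n <- p * q
  measured_rows <- as.integer(measured_rows)
  if (any(measured_rows < 0L | measured_rows >= n)) {
    stop("measured_rows must lie in [0, n)")
  }
  uns <- setdiff(0:(n - 1L), measured_rows)
  if (length(uns) == 0L) {
    return(structure(list(distances = numeric(0), max = 0, mean = 0,
                          histogram = table(numeric(0)), metric = metric),
                     class = "uniformity_report"))
  }
  mi <- measured_rows %/% q; mj <- measured_rows %% q
  dist_one <- function(u) {
    di <- torus_delta(u %/% q, mi, p)
    dj <- torus_delta(u %% q, mj, q)
    d <- switch(metric,
                chebyshev = pmax(di, dj),
                euclidean = sqrt(di^2 + dj^2),
                manhattan = di + dj)
    min(d)
  }
  d <- vapply(uns, dist_one, numeric(1))
  structure(list(distances = d, max = max(d), mean = mean(d),
                 histogram = table(round(d, 6)), metric = metric),
            class = "uniformity_report")
}

#' @export
print.uniformity_report <- function(x, ...) {
  cat(sprintf("Sampling uniformity (%s, torus): %d unsampled sites, max %.3f, mean %.3f\n",
              x$metric, length(x$distances), x$max, x$mean))
  invisible(x)
}

#' Spatial resolution from a reconstructed slit image
#'
#' Follows the slit-profile procedure: average the intensity along lines
#' parallel to the slit, normalize the resulting profile across the slit
#' to `[0, 1]`, and count the pixels whose normalized intensity exceeds
#' 0.5. A width of 1 means the system resolves single encoding pixels.
#'
#' @param recon a `"recon_image"` or numeric matrix containing a slit.
#' @param angle slit orientation in degrees: 0 (vertical slit, profile
#'   across columns), 90 (horizontal), 45 or -45 (diagonal; profiles are
#'   taken over the matching diagonals).
#' @param min_profile_len for diagonal angles, drop profile lines shorter
#'   than this many pixels (corner diagonals average too few samples to be
#'   meaningful; default 3).
#' @return Integer pixel count (the resolution in encoding pixels), with
#'   the normalized profile attached as attribute `"profile"`.
#' @export
spatial_resolution <- function(recon, angle = 0, min_profile_len = 3L) {
  g <- if (inherits(recon, "recon_image")) recon$grid else as.matrix(recon)
  if (!angle %in% c(0, 90, 45, -45)) {
    stop("supported profile angles: 0, 90, 45, -45")
  }
  if (angle == 0) {
    prof <- colMeans(g)
  } else if (angle == 90) {
    prof <- rowMeans(g)
  } else {
    idx <- if (angle == 45) {
      outer(seq_len(nrow(g)), seq_len(ncol(g)), `-`)   # constant along (1,1)
    } else {
      outer(seq_len(nrow(g)), seq_len(ncol(g)), `+`)   # constant along (1,-1)
    }
    grp <- split(as.vector(g), as.vector(idx))
    keep <- lengths(grp) >= min_profile_len
    prof <- vapply(grp[keep], mean, numeric(1))
  }
  rng <- range(prof)
  if (diff(rng) <= 0) stop("flat image: zero dynamic range, no slit profile")
  norm <- (prof - rng[1]) / diff(rng)
  structure(sum(norm > 0.5), profile = norm)
}

#' Reconstruction error metrics
#'
#' Root-mean-square error, maximum absolute error, and RMSE normalized by
#' the dynamic range of the truth.
#'
#' @param recon,truth same-shape numeric matrices (or `"recon_image"`s).
#' @return List with `rmse`, `max_abs`, `nrmse` (`NA` when the truth is
#'   flat).
#' @export
image_error <- function(recon, truth) {
  a <- if (inherits(recon, "recon_image")) recon$grid else as.matrix(recon)
  b <- if (inherits(truth, "thermal_scene")) truth$radiance
       else if (inherits(truth, "recon_image")) truth$grid
       else as.matrix(truth)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  d <- a - b
  rmse <- sqrt(mean(d^2))
  rng <- diff(range(b))
  list(rmse = rmse, max_abs = max(abs(d)),
       nrmse = if (rng > 0) rmse / rng else NA_real_)
}
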