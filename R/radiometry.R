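#' Physical constants and unit helpers
#'
#' `stefan_boltzmann` is the Stefan-Boltzmann constant in W m^-2 K^-4;
#' `celsius_to_kelvin()` / `kelvin_to_celsius()` convert between the
#' interface unit (degrees Celsius) and the internal unit (kelvin; the
#' T^4 radiance law requires absolute temperature).
#'
#' @name units
NULL

#' @rdname units
#' @export
stefan_boltzmann <- 5.67e-8

#' @rdname units
#' @param t_c temperature in degrees Celsius.
#' @export
celsius_to_kelvin <- function(t_c) t_c + 273.15

#' @rdname units
#' @param t_k temperature in kelvin.
#' @export
kelvin_to_celsius <- function(t_k) t_k - 273.15

#' Construct a calibration model directly from known parameters
#'
#' Builds the per-pixel radiometric model `x = C * eps * sigma * T^4 + Delta`
#' from given gain and offset grids (scalars are recycled to `p x q`).
#' Useful for generating synthetic scenes with known ground truth and for
#' round-trip tests.
#'
#' @param p,q grid shape.
#' @param C per-pixel gain (scalar or `p x q` matrix), must be positive.
#' @param Delta per-pixel offset (scalar or `p x q` matrix).
#' @param emissivity scalar emissivity (default 0.98, human skin /
#'   blackbody source).
#' @return An object of class `"calibration_model"`.
#' @export
calibration_model <- function(p, q, C = 1, Delta = 0, emissivity = 0.98) {
  p <- as.integer(p); q <- as.integer(q)
  Cg <- matrix(C, p, q)
  Dg <- matrix(Delta, p, q)
  if (any(Cg <= 0)) stop("gain C must be positive everywhere")
  structure(list(C = Cg, Delta = Dg, emissivity = emissivity,
                 sigma_SB = stefan_boltzmann, p = p, q = q,
                 fit_residuals = NULL),
            class = "calibration_model")
}

#' Radiance predicted by a calibration model
#'
#' Forward radiometric law: `x = C * eps * sigma * T^4 + Delta`, applied
#' per pixel. Inverse of [temperature_map()].
#'
#' @param temperature_K scalar or `p x q` matrix of source temperatures in
#'   kelvin.
#' @param model a `"calibration_model"`.
#' @return A `p x q` radiance matrix in detector units.
#' @export
radiance_from_temperature <- function(temperature_K, model) {
  stopifnot(inherits(model, "calibration_model"))
  Tg <- matrix(temperature_K, model$p, model$q)
  if (any(Tg <= 0)) stop("temperatures must be positive (kelvin)")
  model$C * model$emissivity * model$sigma_SB * Tg^4 + model$Delta
}

#' Fit a per-pixel radiometric calibration from a blackbody sweep
#'
#' Given reconstructed frames of a spatially uniform blackbody source at a
#' set of preset temperatures, fits the linear law
#' `x = C * eps * sigma * T^4 + Delta` pixel by pixel with ordinary least
#' squares (predictor `eps * sigma * T^4`): the slope is the per-pixel
#' gain `C`, the intercept the offset `Delta`. Replicate frames at the
#' same temperature simply enter as additional observations.
#'
#' @param frames list of `"recon_image"` objects (or `p x q` matrices),
#'   one per observation.
#' @param preset_temps_K numeric vector, same length as `frames`: the
#'   source temperature of each frame, in kelvin. At least two distinct
#'   temperatures are required.
#' @param emissivity scalar emissivity (default 0.98).
#' @return A `"calibration_model"` with fitted `C`, `Delta`, per-pixel RMS
#'   residuals in `fit_residuals`, and `n_obs`. Pixels with non-positive
#'   fitted gain are flagged in `bad_gain` (logical grid).
#' @export
fit_calibration <- function(frames, preset_temps_K, emissivity = 0.98) {
  if (length(frames) != length(preset_temps_K)) {
    stop("need one preset temperature per frame")
  }
  if (length(unique(preset_temps_K)) < 2L) {
    stop("calibration requires at least 2 distinct preset temperatures")
  }
  grids <- lapply(frames, function(f)
    if (inherits(f, "recon_image")) f$grid else as.matrix(f))
  d <- dim(grids[[1]])
  if (!all(vapply(grids, function(g) identical(dim(g), d), logical(1)))) {
    stop("all frames must share the same shape")
  }
  p <- d[1]; q <- d[2]
  nf <- length(grids)
  # observations x pixels matrix; pixels in row-major order
  Y <- t(vapply(grids, function(g) as.vector(t(g)), numeric(p * q)))
  t4 <- emissivity * stefan_boltzmann * preset_temps_K^4
  xc <- t4 - mean(t4)
  slope <- as.numeric(crossprod(xc, Y)) / sum(xc^2)
  intercept <- colMeans(Y) - slope * mean(t4)
  fitted <- outer(t4, slope) + rep(intercept, each = nf)
  rms <- sqrt(colMeans((Y - fitted)^2))
  tomat <- function(v) matrix(v, p, q, byrow = TRUE)
  model <- structure(
    list(C = tomat(slope), Delta = tomat(intercept),
         emissivity = emissivity, sigma_SB = stefan_boltzmann,
         p = p, q = q, fit_residuals = tomat(rms),
         bad_gain = tomat(slope <= 0), n_obs = nf),
    class = "calibration_model")
  if (any(model$bad_gain)) {
    warning(sum(model$bad_gain), " pixel(s) fitted with non-positive gain")
  }
  model
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Radiometric calibration model: %d x %d pixels, emissivity %.2f\n",
              x$p, x$q, x$emissivity))
  cat(sprintf("  gain C in [%.4g, %.4g], offset Delta in [%.4g, %.4g]\n",
              min(x$C), max(x$C), min(x$Delta), max(x$Delta)))
  if (!is.null(x$fit_residuals)) {
    cat(sprintf("  per-pixel RMS residual: median %.4g\n",
                stats::median(x$fit_residuals)))
  }
  invisible(x)
}

#' Convert a reconstructed intensity image to a temperature map
#'
#' Inverts the radiometric law per pixel: the fitted offset is subtracted
#' before the fourth root, `T = ((x - Delta) / (C * eps * sigma))^(1/4)`,
#' since that is the algebraic inverse of the calibration model (the
#' bare fourth-root formula without the offset is only valid when
#' `Delta = 0`). Pixels whose radicand is not strictly positive are
#' flagged invalid: a zero radicand yields 0 K at the validity boundary,
#' a negative radicand yields `NA`.
#'
#' @param img a `"recon_image"` (or `p x q` matrix) in detector units.
#' @param model a fitted `"calibration_model"`.
#' @return An object of class `"temperature_map"`: list with `T_K`
#'   (kelvin grid, `NA` where inversion failed), `T_C` (Celsius view),
#'   and logical `valid` grid.
#' @export
temperature_map <- function(img, model) {
  if (!inherits(model, "calibration_model")) {
    stop("model must be a calibration_model (fit one with fit_calibration)")
  }
  g <- if (inherits(img, "recon_image")) img$grid else as.matrix(img)
  if (!all(dim(g) == c(model$p, model$q))) {
    stop("image shape does not match calibration model")
  }
  radicand <- (g - model$Delta) / (model$C * model$emissivity * model$sigma_SB)
  T_K <- matrix(NA_real_, model$p, model$q)
  ok <- radicand >= 0
  T_K[ok] <- radicand[ok]^(1 / 4)
  valid <- radicand > 0
  structure(list(T_K = T_K, T_C = T_K - 273.15, valid = valid,
                 p = model$p, q = model$q),
            class = "temperature_map")
}

#' @export
print.temperature_map <- function(x, ...) {
  v <- x$T_C[x$valid]
  cat(sprintf("Temperature map: %d x %d, %d valid pixels, %.2f to %.2f degC\n",
              x$p, x$q, sum(x$valid), min(v), max(v)))
  invisible(x)
}

#' Mean temperature over a region of interest
#'
#' Arithmetic mean and standard deviation of the valid pixels inside a
#' region mask, in degrees Celsius, with a fever flag against the
#' recommended inner-canthus screening threshold of 37.1 degC.
#'
#' @param map a `"temperature_map"`.
#' @param region logical `p x q` mask selecting the region (e.g. an inner
#'   canthus).
#' @param fever_threshold_C screening threshold in degC (default 37.1).
#' @return List with `mean_C`, `sd_C`, `n_pixels`, `fever` (logical).
#' @export
region_mean_temperature <- function(map, region, fever_threshold_C = 37.1) {
  stopifnot(inherits(map, "temperature_map"))
  region <- as.matrix(region)
  if (!identical(dim(region), dim(map$T_K))) stop("region mask shape mismatch")
  sel <- region & map$valid
  if (!any(sel)) stop("region contains no valid pixels")
  v <- map$T_C[sel]
  list(mean_C = mean(v),
       sd_C = if (length(v) > 1) stats::sd(v) else 0,
       n_pixels = length(v),
       fever = mean(v) >= fever_threshold_C)
}

#' Temperature resolution from a calibration sweep
#'
#' Two complementary definitions, both computed from the recovered
#' per-pixel temperatures at each preset level of a sweep:
#' \itemize{
#'   \item `step_resolution_C`: the smallest preset step such that the
#'     interquartile boxes of adjacent temperature levels do not overlap
#'     (reported as the sweep step when no adjacent boxes overlap, `NA`
#'     when even the full sweep range cannot separate levels);
#'   \item `rms_error_C`: the RMS deviation of recovered pixel
#'     temperatures from their preset values, pooled over the sweep.
#' }
#'
#' @param recovered list of `"temperature_map"` objects (or Celsius
#'   matrices), one or more per preset level.
#' @param preset_C numeric vector of preset temperatures in degC, one per
#'   entry of `recovered`.
#' @return List with `step_resolution_C`, `rms_error_C`, and the per-level
#'   quartile table `levels` (data.frame).
#' @export
temperature_resolution <- function(recovered, preset_C) {
  stopifnot(length(recovered) == length(preset_C))
  vals <- lapply(recovered, function(m) {
    if (inherits(m, "temperature_map")) m$T_C[m$valid] else as.numeric(m)
  })
  lev <- sort(unique(preset_C))
  qs <- t(vapply(lev, function(L) {
    v <- unlist(vals[preset_C == L])
    c(q25 = stats::quantile(v, 0.25, names = FALSE),
      q75 = stats::quantile(v, 0.75, names = FALSE))
  }, numeric(2)))
  levels <- data.frame(preset_C = lev, q25 = qs[, 1], q75 = qs[, 2])
  sep <- if (length(lev) > 1) {
    all(levels$q25[-1] > levels$q75[-nrow(levels)])
  } else TRUE
  step <- if (length(lev) > 1) min(diff(lev)) else NA_real_
  err2 <- mapply(function(v, L) (unlist(v) - L)^2, vals, preset_C,
                 SIMPLIFY = FALSE)
  list(step_resolution_C = if (sep) step else NA_real_,
       rms_error_C = sqrt(mean(unlist(err2))),
       levels = levels)
}
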