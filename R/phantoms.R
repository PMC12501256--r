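# 5 x 7 dot-matrix glyphs (7 rows x 5 cols), "#" = on. X and Z are
# 180-degree rotation symmetric, matching engraved-letter test plates.
glyph_rows <- list(
  "X" = c("#...#",
          "#...#",
          ".#.#.",
          "..#..",
          ".#.#.",
          "#...#",
          "#...#"),
  "Z" = c("#####",
          "....#",
          "...#.",
          "..#..",
          ".#...",
          "#....",
          "#####"),
  "H" = c("#...#",
          "#...#",
          "#...#",
          "#####",
          "#...#",
          "#...#",
          "#...#"),
  "I" = c("#####",
          "..#..",
          "..#..",
          "..#..",
          "..#..",
          "..#..",
          "#####"),
  "O" = c(".###.",
          "#...#",
          "#...#",
          "#...#",
          "#...#",
          "#...#",
          ".###."),
  "T" = c("#####",
          "..#..",
          "..#..",
          "..#..",
          "..#..",
          "..#..",
          "..#.."),
  "L" = c("#....",
          "#....",
          "#....",
          "#....",
          "#....",
          "#....",
          "#####"),
  " " = c(".....",
          ".....",
          ".....",
          ".....",
          ".....",
          ".....",
          ".....")
)

#' Dot-matrix letter mask at grid scale
#'
#' Rasterizes a glyph from a built-in 5 x 7 dot-matrix font, centred on the
#' `p x q` pattern grid.
#'
#' @param glyph single character; one of `names(sptherm:::glyph_rows)`
#'   (includes `"X"`, `"Z"` and `" "` for an empty mask).
#' @param scheme a `"coding_scheme"` (supplies `p`, `q`).
#' @return Logical `p x q` matrix, `TRUE` on glyph strokes.
#' @export
letter_mask <- function(glyph, scheme) {
  stopifnot(inherits(scheme, "coding_scheme"))
  if (!glyph %in% names(glyph_rows)) {
    stop("unsupported glyph '", glyph, "'; supported: ",
         paste(setdiff(names(glyph_rows), " "), collapse = ", "),
         " and ' ' (empty)")
  }
  p <- scheme$p; q <- scheme$q
  if (p < 7L || q < 5L) stop("grid too small for the 5 x 7 font")
  rows <- glyph_rows[[glyph]]
  g <- matrix(FALSE, p, q)
  r0 <- (p - 7L) %/% 2L
  c0 <- (q - 5L) %/% 2L
  for (i in seq_len(7L)) {
    on <- which(strsplit(rows[i], "")[[1]] == "#")
    g[r0 + i, c0 + on] <- TRUE
  }
  g
}

# exact fractional overlap of interval [a, b] with unit cells [k, k+1),
# k = 0..len-1
interval_coverage <- function(a, b, len) {
  k <- 0:(len - 1L)
  pmax(0, pmin(b, k + 1) - pmax(a, k))
}

# coverage grid of a slit of given width (pixels) through `center`
# (row, col in pixel units, grid centre = c(p, q)/2) at one of four angles
slit_coverage <- function(p, q, width, angle, center = c(p / 2, q / 2),
                          supersample = 16L) {
  if (width <= 0) stop("slit width must be positive")
  if (!angle %in% c(0, 90, 45, -45)) {
    stop("supported slit angles: 0, 90, 45, -45 degrees")
  }
  if (center[1] < 0 || center[1] > p || center[2] < 0 || center[2] > q) {
    stop("slit center outside the grid")
  }
  if (angle == 0) {
    # vertical slit: constant column band, exact area overlap
    cov <- interval_coverage(center[2] - width / 2, center[2] + width / 2, q)
    matrix(cov, p, q, byrow = TRUE)
  } else if (angle == 90) {
    cov <- interval_coverage(center[1] - width / 2, center[1] + width / 2, p)
    matrix(cov, p, q)
  } else {
    # rotated slit: supersampled distance to the centre line with
    # direction (1, s) in (row, col) coordinates
    s <- if (angle == 45) 1 else -1
    ss <- as.integer(supersample)
    off <- (seq_len(ss) - 0.5) / ss
    sub_r <- rep(off, times = ss)
    sub_c <- rep(off, each = ss)
    cov <- matrix(0, p, q)
    for (i in seq_len(p)) {
      rr <- (i - 1) + sub_r
      for (j in seq_len(q)) {
        cc <- (j - 1) + sub_c
        # distance from (rr, cc) to line through center with direction (1, s)
        d <- abs(s * (rr - center[1]) - (cc - center[2])) / sqrt(2)
        cov[i, j] <- mean(d <= width / 2)
      }
    }
    cov
  }
}

#' Phantom specification
#'
#' Describes a synthetic thermal scene. Supported kinds:
#' \describe{
#'   \item{uniform}{spatially uniform source at `temperature_C` (a
#'     blackbody field).}
#'   \item{two_level}{background at `background_C` with a rectangular hot
#'     region at `temperature_C` (`hot_rows`, `hot_cols`: index ranges).}
#'   \item{letter}{an engraved-letter plate: glyph strokes at
#'     `temperature_C` over `background_C`.}
#'   \item{slit}{a slit of `slit_width` pixels at `slit_angle` degrees
#'     (0 = vertical, 90 = horizontal, 45 / -45 diagonal) in front of a
#'     source at `temperature_C`; elsewhere `background_C`. Sub-pixel
#'     widths are rasterized by exact area overlap (axis-aligned) or
#'     16x supersampling (diagonal), and partial coverage mixes
#'     radiance, not temperature.}
#'   \item{canthi}{two inner-canthi-like Gaussian hot spots at
#'     `temperature_C` on a skin-level `background_C`, centred in the two
#'     window regions (`centers` overridable, `spot_sigma` in pixels).}
#' }
#'
#' @param kind one of `"uniform"`, `"two_level"`, `"letter"`, `"slit"`,
#'   `"canthi"`.
#' @param temperature_C feature (source) temperature in degC.
#' @param background_C background temperature in degC (defaults: ambient
#'   22 for plates/slits, skin-level 34 for canthi).
#' @param glyph letter for `kind = "letter"`.
#' @param slit_width slit width in encoding pixels (default 0.5).
#' @param slit_angle one of 0, 90, 45, -45.
#' @param slit_center optional `(row, col)` of the slit centre in pixel
#'   units; default: centre of a pixel near the grid middle.
#' @param hot_rows,hot_cols integer ranges for `kind = "two_level"`.
#' @param centers 2 x 2 matrix of `(row, col)` spot centres for
#'   `kind = "canthi"`.
#' @param spot_sigma Gaussian spot width (pixels) for `kind = "canthi"`.
#' @return An object of class `"phantom_spec"` (a validated list).
#' @export
phantom_spec <- function(kind = c("uniform", "two_level", "letter", "slit",
                                  "canthi"),
                         temperature_C = 37.0,
                         background_C = NULL,
                         glyph = "X",
                         slit_width = 0.5, slit_angle = 0,
                         slit_center = NULL,
                         hot_rows = NULL, hot_cols = NULL,
                         centers = NULL, spot_sigma = 1.0) {
  kind <- match.arg(kind)
  if (is.null(background_C)) {
    background_C <- if (kind == "canthi") 34.0 else 22.0
  }
  if (temperature_C <= -273.15 || background_C <= -273.15) {
    stop("temperatures must exceed absolute zero")
  }
  structure(list(kind = kind, temperature_C = temperature_C,
                 background_C = background_C, glyph = glyph,
                 slit_width = slit_width, slit_angle = slit_angle,
                 slit_center = slit_center, hot_rows = hot_rows,
                 hot_cols = hot_cols, centers = centers,
                 spot_sigma = spot_sigma),
            class = "phantom_spec")
}

#' Generate a synthetic thermal scene
#'
#' Rasterizes a [phantom_spec()] onto the scheme's `p x q` grid and
#' converts temperature to radiance through a calibration model, so that
#' phantom, forward simulation, reconstruction and temperature mapping
#' round-trip self-consistently. Where a feature covers a pixel partially
#' (sub-pixel slit), the hot and background radiances are mixed by
#' coverage fraction; the stored temperature grid is then the effective
#' temperature implied by the mixed radiance.
#'
#' @param spec a `"phantom_spec"`.
#' @param scheme a `"coding_scheme"`.
#' @param model a `"calibration_model"` used for the temperature-to-
#'   radiance conversion; default: unit gain, zero offset.
#' @return A `"thermal_scene"` with both `radiance` and `temperature_K`.
#' @export
make_phantom <- function(spec, scheme, model = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(scheme, "coding_scheme"))
  p <- scheme$p; q <- scheme$q
  if (is.null(model)) model <- calibration_model(p, q)
  if (model$p != p || model$q != q) stop("model shape mismatch")
  hot_K <- celsius_to_kelvin(spec$temperature_C)
  bg_K <- celsius_to_kelvin(spec$background_C)
  cov <- switch(
    spec$kind,
    uniform = matrix(1, p, q),
    two_level = {
      hr <- if (is.null(spec$hot_rows)) seq_len(ceiling(p / 2)) else spec$hot_rows
      hc <- if (is.null(spec$hot_cols)) seq_len(q) else spec$hot_cols
      if (any(hr < 1 | hr > p) || any(hc < 1 | hc > q)) {
        stop("hot region outside the grid")
      }
      g <- matrix(0, p, q); g[hr, hc] <- 1; g
    },
    letter = letter_mask(spec$glyph, scheme) * 1,
    slit = {
      ctr <- spec$slit_center
      if (is.null(ctr)) {
        # centre of a pixel near the grid middle, so a half-pixel slit
        # lands inside a single pixel
        ctr <- c(floor(p / 2) + 0.5, floor(q / 2) + 0.5)
      }
      slit_coverage(p, q, spec$slit_width, spec$slit_angle, ctr)
    },
    canthi = {
      ctrs <- spec$centers
      if (is.null(ctrs)) {
        wa <- scheme$split_widths[1]
        ctrs <- rbind(c(p / 2, wa / 2),
                      c(p / 2, wa + scheme$split_widths[2] / 2))
      }
      if (any(ctrs[, 1] < 0 | ctrs[, 1] > p | ctrs[, 2] < 0 | ctrs[, 2] > q)) {
        stop("spot centers outside the grid")
      }
      g <- matrix(0, p, q)
      rr <- matrix(seq_len(p) - 0.5, p, q)
      cc <- matrix(rep(seq_len(q) - 0.5, each = p), p, q)
      for (k in seq_len(nrow(ctrs))) {
        d2 <- (rr - ctrs[k, 1])^2 + (cc - ctrs[k, 2])^2
        g <- pmax(g, exp(-d2 / (2 * spec$spot_sigma^2)))
      }
      g
    }
  )
  hot_rad <- radiance_from_temperature(hot_K, model)
  bg_rad <- radiance_from_temperature(bg_K, model)
  radiance <- bg_rad + cov * (hot_rad - bg_rad)
  # pin fully covered / uncovered pixels to the exact endpoint radiance
  radiance[cov == 1] <- hot_rad[cov == 1]
  radiance[cov == 0] <- bg_rad[cov == 0]
  # effective temperature implied by the (possibly mixed) radiance
  T_eff <- ((radiance - model$Delta) /
              (model$C * model$emissivity * model$sigma_SB))^(1 / 4)
  sc <- thermal_scene(radiance, T_eff)
  sc$coverage <- cov
  sc
}
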