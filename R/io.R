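#' File export and import
#'
#' All objects serialize to plain-text formats: 0/1 or numeric CSV for
#' grids, JSON sidecars for metadata, plus PNG previews (8-bit grayscale;
#' the CSV carries full precision and the sidecar records the min-max
#' scaling applied to the PNG).
#'
#' @name sptherm-io
NULL

write_grid_csv <- function(grid, path) {
  utils::write.table(grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}

read_grid_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                   colClasses = "numeric", na.strings = ""))
  dimnames(m) <- NULL
  m
}

write_grid_png <- function(grid, path, na_value = 0) {
  g <- as.matrix(grid)
  g[is.na(g)] <- na_value
  rng <- range(g)
  scaled <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else g * 0
  png::writePNG(scaled, path)
  invisible(list(min = rng[1], max = rng[2]))
}

#' Export an S-matrix
#'
#' Writes `<prefix>.csv` (full 0/1 matrix), `<prefix>_first_row.csv`,
#' `<prefix>.png` (preview) and `<prefix>.json` (sidecar with `p`, `q`,
#' `n`, construction name).
#'
#' @param S an `"smatrix"`.
#' @param prefix output path prefix.
#' @return Invisibly, the sidecar path.
#' @export
write_smatrix <- function(S, prefix) {
  stopifnot(inherits(S, "smatrix"))
  write_grid_csv(S$matrix, paste0(prefix, ".csv"))
  write_grid_csv(matrix(S$first_row, nrow = 1), paste0(prefix, "_first_row.csv"))
  write_grid_png(S$matrix, paste0(prefix, ".png"))
  side <- list(p = S$p, q = S$q, n = S$n, construction = S$construction)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(paste0(prefix, ".json"))
}

#' Import an S-matrix written by [write_smatrix()]
#'
#' @param prefix path prefix used at export.
#' @return An `"smatrix"` object (validated).
#' @export
read_smatrix <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  M <- read_grid_csv(paste0(prefix, ".csv"))
  storage.mode(M) <- "integer"
  S <- structure(list(p = side$p, q = side$q, n = side$n,
                      first_row = M[1, ], matrix = M,
                      construction = side$construction),
                 class = "smatrix")
  rep <- validate_smatrix(S)
  if (!attr(rep, "valid")) stop("imported matrix fails S-matrix validation")
  S
}

#' Export a stripe layout
#'
#' Writes the band raster as CSV (opaque cells empty) and PNG preview,
#' with a JSON sidecar recording `p`, `q`, `n`, `m`, marker coordinates,
#' pixel pitch and magnification.
#'
#' @param stripe a `"stripe_layout"`.
#' @param prefix output path prefix.
#' @param scheme optional `"coding_scheme"` supplying physical constants
#'   for the sidecar.
#' @return Invisibly, the sidecar path.
#' @export
write_stripe <- function(stripe, prefix, scheme = NULL) {
  stopifnot(inherits(stripe, "stripe_layout"))
  write_grid_csv(stripe$grid, paste0(prefix, ".csv"))
  write_grid_png(stripe$grid, paste0(prefix, ".png"))
  side <- list(p = stripe$p, q = stripe$q, n = stripe$n, m = stripe$m,
               runway = stripe$runway, offset = stripe$offset,
               markers = stripe$markers,
               pixel_pitch = if (!is.null(scheme)) scheme$pixel_pitch else NULL,
               magnification = if (!is.null(scheme)) scheme$magnification else NULL)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' Serialize / read back a scan record
#'
#' JSON carries all metadata (measurement rows, noise level, gain, seed)
#' plus the signal vector; a companion CSV holds the `(row, bucket)`
#' table.
#'
#' @param record a `"scan_record"`.
#' @param prefix output path prefix.
#' @return Invisibly, the JSON path.
#' @export
write_scan_record <- function(record, prefix) {
  stopifnot(inherits(record, "scan_record"))
  obj <- unclass(record)
  jsonlite::write_json(obj, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  utils::write.csv(data.frame(row = record$measured_rows,
                              bucket = record$bucket),
                   paste0(prefix, ".csv"), row.names = FALSE)
  invisible(paste0(prefix, ".json"))
}

#' @rdname write_scan_record
#' @export
read_scan_record <- function(prefix) {
  obj <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  obj$measured_rows <- as.integer(obj$measured_rows)
  structure(obj, class = "scan_record")
}

#' Export a reconstructed image
#'
#' CSV with full precision, 8-bit PNG preview, JSON sidecar recording the
#' min-max scaling used for the preview.
#'
#' @param img a `"recon_image"` (or matrix).
#' @param prefix output path prefix.
#' @return Invisibly, the sidecar path.
#' @export
write_image <- function(img, prefix) {
  g <- if (inherits(img, "recon_image")) img$grid else as.matrix(img)
  write_grid_csv(g, paste0(prefix, ".csv"))
  sc <- write_grid_png(g, paste0(prefix, ".png"))
  jsonlite::write_json(list(rows = nrow(g), cols = ncol(g),
                            png_scale_min = sc$min, png_scale_max = sc$max),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' @rdname write_image
#' @export
read_image <- function(prefix) {
  g <- read_grid_csv(paste0(prefix, ".csv"))
  structure(list(grid = g, p = nrow(g), q = ncol(g), n = nrow(g) * ncol(g)),
            class = "recon_image")
}

#' Export a calibration model / temperature map
#'
#' Per-pixel grids as CSV (temperatures in degC at the interface), scalar
#' constants in a JSON sidecar.
#'
#' @param model a `"calibration_model"`.
#' @param prefix output path prefix.
#' @return Invisibly, the sidecar path.
#' @export
write_calibration <- function(model, prefix) {
  stopifnot(inherits(model, "calibration_model"))
  write_grid_csv(model$C, paste0(prefix, "_C.csv"))
  write_grid_csv(model$Delta, paste0(prefix, "_Delta.csv"))
  if (!is.null(model$fit_residuals)) {
    write_grid_csv(model$fit_residuals, paste0(prefix, "_residuals.csv"))
  }
  jsonlite::write_json(list(emissivity = model$emissivity,
                            sigma_SB = model$sigma_SB,
                            p = model$p, q = model$q),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' @rdname write_calibration
#' @export
read_calibration <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  C <- read_grid_csv(paste0(prefix, "_C.csv"))
  Delta <- read_grid_csv(paste0(prefix, "_Delta.csv"))
  res_path <- paste0(prefix, "_residuals.csv")
  structure(list(C = C, Delta = Delta, emissivity = side$emissivity,
                 sigma_SB = side$sigma_SB, p = side$p, q = side$q,
                 fit_residuals = if (file.exists(res_path))
                   read_grid_csv(res_path) else NULL),
            class = "calibration_model")
}

#' @rdname write_calibration
#' @param map a `"temperature_map"`.
#' @export
write_temperature_map <- function(map, prefix) {
  stopifnot(inherits(map, "temperature_map"))
  write_grid_csv(map$T_C, paste0(prefix, "_degC.csv"))
  write_grid_csv(map$valid * 1L, paste0(prefix, "_valid.csv"))
  jsonlite::write_json(list(p = map$p, q = map$q, units = "degC"),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(paste0(prefix, ".json"))
}
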