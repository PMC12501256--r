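#' Coding scheme: pattern geometry and compressed diagonal scan
#'
#' Bundles the geometry of a scanning acquisition: the twin-prime pattern
#' shape `p x q`, the scan length `m` (number of bucket signals collected,
#' `m <= n`), the ordered measurement-row indices visited by the diagonal
#' scan, the widths of the two split window parts, flip flags applied to
#' each part, and the physical constants of the optical layout (encoding
#' pixel pitch on the mask plate and the object-to-mask magnification).
#'
#' The diagonal scan visits measurement rows `u_k = (q + 1) * k mod n`;
#' because `gcd(q + 1, n) = 1` for a twin-prime order these are pairwise
#' distinct for any `m <= n`, and for `m = n` they form a permutation of
#' all rows.
#'
#' @param p,q twin primes (`q = p + 2`).
#' @param m scan length, number of patterns measured; defaults to `n = p*q`
#'   (a full scan). The deployed 11 x 13 system uses `m = 91`.
#' @param pixel_pitch physical encoding-pixel size on the mask plate, in mm
#'   (default 0.25, i.e. 250 micrometres).
#' @param magnification object-to-mask demagnification ratio (default 4, so
#'   each 0.25 mm mask pixel samples 1 mm at the object plane).
#' @param stripe_separation_mask physical separation of the two encoded
#'   stripes on the mask plate, in mm (default 7.5).
#' @param flip_a,flip_b per-part flip flags, each a subset of
#'   `c("h", "v")` (horizontal = reverse columns, vertical = reverse rows);
#'   default none.
#' @param scan `"diagonal"` (the compressed diagonal scan, default) or
#'   `"linear"` (conventional scan of consecutive rows `0:(m-1)`, kept for
#'   uniformity comparisons).
#' @return An object of class `"coding_scheme"`.
#' @examples
#' sch <- coding_scheme(11, 13, m = 91)
#' length(sch$measured_rows)  # 91
#' sch$split_widths           # 7 6
#' @export
coding_scheme <- function(p, q, m = NULL,
                          pixel_pitch = 0.25, magnification = 4,
                          stripe_separation_mask = 7.5,
                          flip_a = character(), flip_b = character(),
                          scan = c("diagonal", "linear")) {
  scan <- match.arg(scan)
  if (!is_prime(p) || !is_prime(q) || q - p != 2L) {
    stop("p, q must be twin primes with q = p + 2")
  }
  p <- as.integer(p); q <- as.integer(q)
  n <- p * q
  if (is.null(m)) m <- n
  m <- as.integer(m)
  if (m < 1L || m > n) stop("scan length m must satisfy 1 <= m <= n = ", n)
  stopifnot(all(flip_a %in% c("h", "v")), all(flip_b %in% c("h", "v")))
  structure(
    list(
      p = p, q = q, n = n, m = m, scan = scan,
      measured_rows = if (scan == "diagonal") diagonal_scan_rows(p, q, m)
                      else 0:(m - 1L),
      split_widths = c((q + 1L) %/% 2L, (q - 1L) %/% 2L),
      flip_config = list(a = flip_a, b = flip_b),
      pixel_pitch = pixel_pitch,
      magnification = magnification,
      stripe_separation_mask = stripe_separation_mask
    ),
    class = "coding_scheme"
  )
}

#' @export
print.coding_scheme <- function(x, ...) {
  cat(sprintf("Coding scheme: %d x %d patterns (n = %d), scan length m = %d\n",
              x$p, x$q, x$n, x$m))
  cat(sprintf("  split widths %d + %d, pixel pitch %g mm, magnification %g:1\n",
              x$split_widths[1], x$split_widths[2], x$pixel_pitch,
              x$magnification))
  invisible(x)
}

#' Diagonal compressed-scan measurement rows
#'
#' The bucket signals, arranged row-major on the `p x q` grid, are acquired
#' along the 2D diagonal: positions (0,0), (1,1), ..., (m-1, m-1) with both
#' coordinates taken modulo the grid. In linear (row-major) index this is
#' `u_k = (q + 1) * k mod n`. The indices are pairwise distinct as long as
#' `m` does not exceed the cycle length `n / gcd(q + 1, n)`; since
#' `gcd(q + 1, p * q) = gcd(3, p)`, the diagonal is a full permutation for
#' every twin-prime pair except (3, 5), whose scan cycles after 5 steps.
#' Requests beyond the cycle length are rejected (repeated rows measure
#' nothing new).
#'
#' @param p,q twin primes.
#' @param m number of scan steps, `m <= n`.
#' @return Integer vector of `m` distinct 0-based row indices, starting at 0.
#' @examples
#' diagonal_scan_rows(11, 13, 3)  # 0 14 28
#' @export
diagonal_scan_rows <- function(p, q, m) {
  n <- as.integer(p) * as.integer(q)
  m <- as.integer(m)
  if (m > n) stop("m must not exceed n = ", n)
  if (m < 1L) stop("m must be at least 1")
  cycle <- n %/% gcd_int((q + 1L) %% n, n)
  if (m > cycle) {
    stop("diagonal scan of the (", p, ", ", q, ") grid repeats after ",
         cycle, " steps; m must not exceed ", cycle)
  }
  as.integer(((q + 1L) * (0:(m - 1L))) %% n)
}

gcd_int <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' 2D encoding pattern for one measurement row
#'
#' Row `u` of the S-matrix, reshaped row-major into a `p x q` grid:
#' `grid[i, j] = S[u, q*i + j]` (0-based). Each pattern contains exactly
#' `(n + 1) / 2` transmissive pixels.
#'
#' @param S an `"smatrix"`.
#' @param u 0-based row index in `[0, n)`.
#' @return An object of class `"encoding_pattern"`: list with `row_index`
#'   and the binary `grid`.
#' @export
pattern_for_row <- function(S, u) {
  stopifnot(inherits(S, "smatrix"))
  u <- as.integer(u)
  if (u < 0L || u >= S$n) stop("row index u must be in [0, ", S$n - 1L, "]")
  grid <- matrix(S$matrix[u + 1L, ], nrow = S$p, ncol = S$q, byrow = TRUE)
  structure(list(row_index = u, grid = grid, p = S$p, q = S$q),
            class = "encoding_pattern")
}

#' Tiled pattern matrix
#'
#' The doubly periodic extension of the base pattern:
#' `T[a, b] = S[0, (q*a + b) mod n]` (0-based). Any `p x q` crop whose
#' top-left corner sits at `(k, k)` equals the encoding pattern of
#' measurement row `(q + 1) * k mod n`, which is what makes a single
#' diagonal stripe step through the compressed scan's rows.
#'
#' @param S an `"smatrix"`.
#' @param rows,cols extents of the tiling (default one pattern plus a full
#'   diagonal period).
#' @return A binary integer matrix of dimension `rows x cols`.
#' @export
tiled_matrix <- function(S, rows = S$p + S$n - 1L, cols = S$q + S$n - 1L) {
  stopifnot(inherits(S, "smatrix"))
  if (rows < S$p || cols < S$q) stop("tiling extents must cover one pattern")
  idx <- outer(0:(rows - 1L), 0:(cols - 1L),
               function(a, b) (S$q * a + b) %% S$n) + 1L
  out <- matrix(S$first_row[idx], rows, cols)
  storage.mode(out) <- "integer"
  out
}

#' Diagonally aggregated scanning stripe
#'
#' Lays the `m` encoding patterns of the compressed scan along the diagonal
#' of the tiled matrix, producing the band that is physically fabricated as
#' one continuous mask stripe: translating a `p x q` window down the band by
#' `k` steps (one step = one pixel down and one right in logical
#' coordinates; in the lab frame the stripe is mounted at 45 degrees so the
#' translation is purely vertical) exposes the pattern of measurement row
#' `(q + 1) * k mod n`. Cells outside the band are opaque (`NA` in the
#' returned grid).
#'
#' When `runway = TRUE`, four auxiliary L-shaped run-way markers are
#' appended (two before the first pattern, two after the last) to signal
#' the onset and completion of encoding, and a single alignment pixel is
#' placed at the same horizontal position on the top and bottom edges.
#' Markers live outside the band and never enter the measurement matrix;
#' their geometry (`runway_size`) is configurable.
#'
#' @param S an `"smatrix"`.
#' @param m number of scan positions (`m <= n`).
#' @param runway logical; append run-way and alignment markers.
#' @param runway_size side length in pixels of each L-shaped marker
#'   (default 3).
#' @return An object of class `"stripe_layout"`: list with the band `grid`
#'   (0/1/NA), `offset` (rows/cols prepended before the band, 0-based),
#'   `markers` (data.frame of marker type and 0-based top-left positions),
#'   `p`, `q`, `n`, `m`.
#' @seealso [extract_stripe_pattern()]
#' @export
aggregate_stripe <- function(S, m, runway = FALSE, runway_size = 3L) {
  stopifnot(inherits(S, "smatrix"))
  m <- as.integer(m)
  if (m > S$n) stop("m must not exceed n = ", S$n)
  if (m < 1L) stop("m must be at least 1")
  p <- S$p; q <- S$q
  band_r <- m - 1L + p
  band_c <- m - 1L + q
  T_ <- tiled_matrix(S, band_r, band_c)
  grid <- matrix(NA_integer_, band_r, band_c)
  for (k in 0:(m - 1L)) {
    grid[k + seq_len(p), k + seq_len(q)] <- T_[k + seq_len(p), k + seq_len(q)]
  }
  markers <- data.frame(type = character(), row = integer(), col = integer())
  offset <- c(0L, 0L)
  if (runway) {
    rs <- as.integer(runway_size)
    pad <- rs + 1L
    full <- matrix(NA_integer_, band_r + 2L * pad + 2L, band_c)
    # one-pixel top and bottom alignment rows, then runway pad, then band
    offset <- c(pad + 1L, 0L)
    full[offset[1] + seq_len(band_r), ] <- grid
    Lshape <- function(top, left, flip) {
      # L drawn as a vertical and a horizontal bar of runway_size pixels
      cells <- rbind(
        cbind(top + 0:(rs - 1L), left),
        cbind(top + rs - 1L, left + 0:(rs - 1L))
      )
      if (flip) cells[, 2] <- 2L * left + rs - 1L - cells[, 2]
      cells
    }
    place <- function(full, cells) {
      cells <- cells[cells[, 2] >= 1 & cells[, 2] <= ncol(full), , drop = FALSE]
      full[cells] <- 1L
      full
    }
    # two L markers before the first pattern, two after the last
    pre_top <- 2L
    post_top <- nrow(full) - rs
    marks <- list(
      list("runway", pre_top, 1L, FALSE),
      list("runway", pre_top, band_c - rs + 1L, TRUE),
      list("runway", post_top, 1L, FALSE),
      list("runway", post_top, band_c - rs + 1L, TRUE)
    )
    for (mk in marks) {
      full <- place(full, Lshape(mk[[2]], mk[[3]], mk[[4]]))
      markers <- rbind(markers, data.frame(type = mk[[1]],
                                           row = mk[[2]] - 1L,
                                           col = mk[[3]] - 1L))
    }
    # single alignment pixel, same horizontal position top and bottom
    acol <- (band_c + 1L) %/% 2L
    full[1L, acol] <- 1L
    full[nrow(full), acol] <- 1L
    markers <- rbind(markers,
                     data.frame(type = "alignment", row = 0L, col = acol - 1L),
                     data.frame(type = "alignment", row = nrow(full) - 1L,
                                col = acol - 1L))
    grid <- full
  }
  structure(list(grid = grid, offset = offset, markers = markers,
                 p = p, q = q, n = S$n, m = m, runway = runway),
            class = "stripe_layout")
}

#' Extract the encoding pattern at a scan position from a stripe
#'
#' Crops the `p x q` window at diagonal position `k` out of the aggregated
#' band; the result must equal `pattern_for_row(S, (q + 1) * k mod n)`.
#'
#' @param stripe a `"stripe_layout"`.
#' @param k 0-based scan position, `0 <= k < m`.
#' @return A binary `p x q` integer matrix.
#' @export
extract_stripe_pattern <- function(stripe, k) {
  stopifnot(inherits(stripe, "stripe_layout"))
  k <- as.integer(k)
  if (k < 0L || k >= stripe$m) stop("scan position k must be in [0, m)")
  r0 <- stripe$offset[1] + k
  c0 <- stripe$offset[2] + k
  out <- stripe$grid[r0 + seq_len(stripe$p), c0 + seq_len(stripe$q)]
  storage.mode(out) <- "integer"
  out
}

apply_flips <- function(g, flips) {
  if ("h" %in% flips) g <- g[, rev(seq_len(ncol(g))), drop = FALSE]
  if ("v" %in% flips) g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
  g
}

#' Split an encoding pattern into the two window parts
#'
#' Each `p x q` pattern is divided vertically into a `p x (q+1)/2` part and
#' a `p x (q-1)/2` part (the two mask windows covering the left and right
#' regions of the field of view), and each part is optionally flipped
#' according to the scheme's `flip_config`. [reassemble_pattern()] inverts
#' the operation exactly.
#'
#' @param pat an `"encoding_pattern"`, or a `p x q` matrix.
#' @param scheme a `"coding_scheme"` (supplies split widths and flips).
#' @return List with elements `a` (`p x (q+1)/2`) and `b` (`p x (q-1)/2`).
#' @export
split_pattern <- function(pat, scheme) {
  stopifnot(inherits(scheme, "coding_scheme"))
  g <- if (inherits(pat, "encoding_pattern")) pat$grid else as.matrix(pat)
  q <- scheme$q
  if (ncol(g) != q) stop("pattern has ", ncol(g), " columns, expected q = ", q)
  wa <- scheme$split_widths[1]
  a <- g[, seq_len(wa), drop = FALSE]
  b <- g[, wa + seq_len(q - wa), drop = FALSE]
  list(a = apply_flips(a, scheme$flip_config$a),
       b = apply_flips(b, scheme$flip_config$b))
}

#' Reassemble a split pattern
#'
#' Exact inverse of [split_pattern()]: undoes the per-part flips and
#' concatenates the two parts back into the full `p x q` grid.
#'
#' @param part_a,part_b the two parts, widths `(q+1)/2` and `(q-1)/2`.
#' @param scheme a `"coding_scheme"`.
#' @return A `p x q` matrix.
#' @export
reassemble_pattern <- function(part_a, part_b, scheme) {
  stopifnot(inherits(scheme, "coding_scheme"))
  wa <- scheme$split_widths[1]; wb <- scheme$split_widths[2]
  if (ncol(part_a) != wa || ncol(part_b) != wb) {
    stop("part widths (", ncol(part_a), ", ", ncol(part_b),
         ") do not match scheme widths (", wa, ", ", wb, ")")
  }
  if (nrow(part_a) != nrow(part_b)) stop("parts must have equal heights")
  # flips are involutions
  a <- apply_flips(part_a, scheme$flip_config$a)
  b <- apply_flips(part_b, scheme$flip_config$b)
  cbind(a, b)
}

#' Object-plane geometry implied by a coding scheme
#'
#' Converts the mask-plate constants to object-plane quantities: the
#' separation of the two imaged regions and the area sampled by one
#' encoding pixel, both scaled by the magnification ratio.
#'
#' @param scheme a `"coding_scheme"`.
#' @return List with `region_separation_mm` (stripe separation on the mask
#'   times magnification) and `pixel_sampling_mm` (pixel pitch times
#'   magnification).
#' @examples
#' object_plane_geometry(coding_scheme(11, 13, 91))
#' # 30 mm separation, 1 mm per pixel
#' @export
object_plane_geometry <- function(scheme) {
  stopifnot(inherits(scheme, "coding_scheme"))
  list(
    region_separation_mm = scheme$stripe_separation_mask * scheme$magnification,
    pixel_sampling_mm = scheme$pixel_pitch * scheme$magnification
  )
}
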