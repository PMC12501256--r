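test_that("pattern_for_row is the row-major reshape of the matrix row", {
  for (u in c(0, 3, 14)) {
    pat <- pattern_for_row(S15, u)
    for (i in 0:2) for (j in 0:4) {
      expect_equal(pat$grid[i + 1, j + 1], S15$matrix[u + 1, 5 * i + j + 1])
    }
    expect_equal(sum(pat$grid), 8)
  }
  expect_error(pattern_for_row(S15, 15), "range|\\[0")
  p143 <- pattern_for_row(S143, 0)
  expect_equal(dim(p143$grid), c(11, 13))
  expect_equal(sum(p143$grid), 72)
})

test_that("tiled matrix crops reproduce diagonal-scan patterns", {
  T143 <- tiled_matrix(S143, 30, 30)
  expect_identical(T143[1:11, 1:13], pattern_for_row(S143, 0)$grid)
  # crop at k = 1 equals the pattern of row (q+1)*1 mod n = 14
  expect_identical(T143[1 + 1:11, 1 + 1:13], pattern_for_row(S143, 14)$grid)
  # invariance under shifts of n in the flattened index
  T15 <- tiled_matrix(S15)
  expect_identical(T15[1, 1], T15[4, 1])  # shift by p rows = q*p = n flat
})

test_that("diagonal scan rows are the (q+1)-step progression, distinct", {
  expect_identical(diagonal_scan_rows(11, 13, 3), c(0L, 14L, 28L))
  full <- diagonal_scan_rows(11, 13, 143)
  expect_setequal(full, 0:142)
  expect_equal(length(unique(diagonal_scan_rows(11, 13, 91))), 91)
  expect_error(diagonal_scan_rows(11, 13, 144), "exceed")
  # distinctness wherever the diagonal is a permutation
  for (pq in list(c(5, 7), c(11, 13))) {
    n <- pq[1] * pq[2]
    expect_equal(length(unique(diagonal_scan_rows(pq[1], pq[2], n))), n)
  }
  # (3, 5): the diagonal cycles after 5 steps and repeats are refused
  expect_identical(diagonal_scan_rows(3, 5, 5), as.integer((6 * 0:4) %% 15))
  expect_error(diagonal_scan_rows(3, 5, 6), "repeats after 5")
})

test_that("aggregated stripe crops reproduce every scan pattern", {
  st <- aggregate_stripe(S15, 10)
  for (k in 0:9) {
    expect_identical(extract_stripe_pattern(st, k),
                     pattern_for_row(S15, (6L * k) %% 15L)$grid)
  }
  st1 <- aggregate_stripe(S15, 1)
  expect_identical(st1$grid, pattern_for_row(S15, 0)$grid)
})

test_that("stripe equivalence: band-crop bucket equals S-row inner product", {
  # the physical claim behind the design: measuring through the stripe
  # window at position k is the same measurement as row (q+1)k of S
  set.seed(42)
  scene <- matrix(runif(15), 3, 5)
  st <- aggregate_stripe(S15, 15)
  rows <- (6L * (0:14)) %% 15L   # crop k maps to row (q+1)k mod n, repeats ok
  for (k in 0:14) {
    crop <- extract_stripe_pattern(st, k)
    expect_equal(sum(crop * scene), naive_bucket(S15, scene, rows[k + 1]),
                 tolerance = 1e-12)
  }
})

test_that("runway markers: four L-shapes plus two alignment pixels", {
  st <- aggregate_stripe(S15, 10, runway = TRUE)
  expect_equal(sum(st$markers$type == "runway"), 4)
  expect_equal(sum(st$markers$type == "alignment"), 2)
  # markers do not disturb the measurement patterns
  for (k in c(0, 5, 9)) {
    expect_identical(extract_stripe_pattern(st, k),
                     pattern_for_row(S15, (6L * k) %% 15L)$grid)
  }
  # alignment pixels share one horizontal position, top and bottom edge
  al <- st$markers[st$markers$type == "alignment", ]
  expect_equal(length(unique(al$col)), 1)
  expect_setequal(al$row, c(0L, nrow(st$grid) - 1L))
  st_off <- aggregate_stripe(S15, 10, runway = FALSE)
  expect_equal(nrow(st_off$markers), 0)
})

test_that("split widths follow ((q+1)/2, (q-1)/2) and conserve ones", {
  sch <- scheme143()
  expect_identical(sch$split_widths, c(7L, 6L))
  expect_identical(scheme15()$split_widths, c(3L, 2L))
  pat <- pattern_for_row(S143, 17)
  parts <- split_pattern(pat, sch)
  expect_equal(dim(parts$a), c(11, 7))
  expect_equal(dim(parts$b), c(11, 6))
  expect_equal(sum(parts$a) + sum(parts$b), 72)
})

test_that("split/reassemble round-trips exactly, with and without flips", {
  set.seed(7)
  for (flips in list(list(a = character(), b = character()),
                     list(a = "h", b = "v"),
                     list(a = c("h", "v"), b = "h"))) {
    sch <- coding_scheme(3, 5, 5, flip_a = flips$a, flip_b = flips$b)
    for (rep in 1:5) {
      g <- matrix(rbinom(15, 1, 0.5), 3, 5)
      parts <- split_pattern(g, sch)
      expect_identical(reassemble_pattern(parts$a, parts$b, sch), g)
    }
  }
  # flips change the parts but not the round trip
  schf <- coding_scheme(3, 5, 5, flip_a = "h")
  g <- matrix(1:15, 3, 5, byrow = TRUE)
  expect_false(identical(split_pattern(g, schf)$a,
                         split_pattern(g, scheme15())$a))
  expect_error(reassemble_pattern(matrix(0, 3, 2), matrix(0, 3, 2),
                                  scheme15()), "widths")
})

test_that("object-plane geometry follows pitch and magnification", {
  geo <- object_plane_geometry(scheme143())
  expect_equal(geo$region_separation_mm, 30)
  expect_equal(geo$pixel_sampling_mm, 1)
})
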