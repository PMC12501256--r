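test_that("fully sampled records interpolate to the identity", {
  set.seed(1)
  s <- matrix(runif(35), 5, 7)
  rec <- simulate_scan(s, S35, scheme35(35))
  yt <- laplace_interpolate(rec)
  full <- numeric(35); full[rec$measured_rows + 1] <- rec$bucket
  expect_identical(yt$values, full)
  expect_true(all(yt$measured_mask))
})

test_that("a single missing value equals the mean of its four neighbors", {
  # leave exactly one linear index unmeasured; its harmonic value must be
  # the average of u+1, u-1, u+q, u-q (mod n)
  n <- 15L; q <- 5L
  set.seed(2)
  y <- runif(n)
  for (u in c(0L, 7L, 14L)) {
    rows <- setdiff(0:(n - 1L), u)
    rec <- list(measured_rows = rows, bucket = y[rows + 1L], n = n, q = q)
    yt <- laplace_interpolate(rec)
    nb <- (c(u + 1L, u - 1L, u + q, u - q) %% n) + 1L
    expect_equal(yt$values[u + 1L], mean(y[nb]), tolerance = 1e-12)
    expect_identical(yt$values[rows + 1L], y[rows + 1L])
  }
})

test_that("constants are harmonic and the Laplace equation holds everywhere", {
  sch <- scheme143(91)
  rec <- simulate_scan(matrix(3.7, 11, 13), S143, sch)
  yt <- laplace_interpolate(rec, sch)
  expect_all_equal(yt$values, rep(3.7 * 72, 143), tol = 1e-9)
  # non-constant scene: residual of the interpolation equation at every
  # unmeasured index
  set.seed(5)
  rec2 <- simulate_scan(random_smooth_scene(11, 13), S143, sch)
  yt2 <- laplace_interpolate(rec2, sch)
  v <- yt2$values; n <- 143L; q <- 13L
  for (u in which(!yt2$measured_mask) - 1L) {
    nb <- (c(u + 1L, u - 1L, u + q, u - q) %% n) + 1L
    expect_lt(abs(v[u + 1L] - mean(v[nb])), 1e-10)
  }
})

test_that("direct sparse solve matches the Gauss-Seidel oracle", {
  # order-15 problems with random measured subsets (unknowns neighbor
  # unknowns), plus the diagonal scan itself
  set.seed(8)
  x <- runif(15, 1, 2)
  y <- as.numeric(S15$matrix %*% x)
  for (m in c(4, 8, 12)) {
    rows <- sort(sample(0:14, m))
    rec <- list(measured_rows = rows, bucket = y[rows + 1], n = 15L, q = 5L)
    direct <- laplace_interpolate(rec)
    gs <- sptherm:::laplace_interpolate_gs(rec, tol = 1e-12)
    expect_all_equal(direct$values, gs$values, tol = 1e-8)
  }
  sch <- scheme15(5)
  rec <- simulate_scan(matrix(x, 3, 5, byrow = TRUE), S15, sch)
  expect_all_equal(laplace_interpolate(rec, sch)$values,
                   sptherm:::laplace_interpolate_gs(rec, sch,
                                                    tol = 1e-12)$values,
                   tol = 1e-8)
})

test_that("interpolated values respect the discrete maximum principle", {
  set.seed(13)
  for (rep in 1:10) {
    m <- sample(3:14, 1)
    rows <- sort(sample(0:14, m))
    rec <- list(measured_rows = rows, bucket = runif(m, -2, 5), n = 15L, q = 5L)
    yt <- laplace_interpolate(rec)
    unm <- yt$values[!yt$measured_mask]
    expect_true(all(unm >= min(rec$bucket) - 1e-12))
    expect_true(all(unm <= max(rec$bucket) + 1e-12))
  }
})

test_that("noiseless full scan reconstructs any scene exactly", {
  set.seed(21)
  for (rep in 1:20) {
    s <- matrix(runif(143, 0, 10), 11, 13)
    rec <- simulate_full_scan(s, S143)
    img <- reconstruct(laplace_interpolate(rec), S143)
    expect_lt(max(abs(img$grid - s)), 1e-9)
  }
  expect_true(all(reconstruct(numeric(143), S143)$grid == 0))
  expect_error(reconstruct(numeric(10), S143), "length")
})

test_that("reconstruction error decreases with scan length on smooth scenes", {
  set.seed(31)
  ms <- c(12, 24, 35)
  mean_rmse <- sapply(ms, function(m) {
    sch <- scheme35(m)
    mean(replicate(50, {
      sc <- random_smooth_scene(5, 7)
      img <- reconstruct(laplace_interpolate(simulate_scan(sc, S35, sch), sch),
                         S35)
      image_error(img, sc$radiance)$rmse
    }))
  })
  expect_true(all(diff(mean_rmse) <= 0))
  expect_lt(mean_rmse[3], 1e-9)
})

test_that("compressed scan of a smooth scene reconstructs accurately", {
  set.seed(41)
  sch <- scheme143(91)
  errs <- replicate(10, {
    sc <- random_smooth_scene(11, 13)
    img <- reconstruct(laplace_interpolate(simulate_scan(sc, S143, sch), sch),
                       S143)
    image_error(img, sc$radiance)$nrmse
  })
  expect_lt(mean(errs), 0.05)
})

test_that("field-of-view reassembly returns the two window regions", {
  set.seed(51)
  img <- reconstruct(runif(143), S143)
  sch <- scheme143()
  fov <- reassemble_fov(img, sch)
  expect_equal(dim(fov$a), c(11, 7))
  expect_equal(dim(fov$b), c(11, 6))
  expect_equal(fov$rotation_deg, c(-45, 45))
  expect_identical(reassemble_pattern(fov$a, fov$b, sch), img$grid)
  # flips honored and invertible
  schf <- coding_scheme(11, 13, 91, flip_a = "v", flip_b = "h")
  fovf <- reassemble_fov(img, schf)
  expect_false(identical(fovf$a, fov$a))
  expect_identical(reassemble_pattern(fovf$a, fovf$b, schf), img$grid)
})
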