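test_that("localization finds isolated spots with sub-pixel accuracy", {
  expect_equal(nrow(localize_emitters(matrix(0, 32, 32), 10)), 0)
  img <- oracle_spot(c(40, 40), 10, 25, sigma = 1.5, amp = 1000) +
    oracle_spot(c(40, 40), 30, 25, sigma = 1.5, amp = 800)
  loc <- localize_emitters(img, 50)
  expect_equal(nrow(loc), 2)
  img1 <- oracle_spot(c(40, 40), 10.30, 12.75, sigma = 1.5, amp = 1000)
  loc1 <- localize_emitters(img1, 20)
  expect_equal(nrow(loc1), 1)
  expect_lt(abs(loc1$x - 10.30), 0.05)
  expect_lt(abs(loc1$y - 12.75), 0.05)
})

test_that("affine fitting recovers exact correspondences to machine precision", {
  pts <- withr::with_seed(7, tibble::tibble(x = runif(50, 0, 200),
                                            y = runif(50, 0, 200)))
  ident <- fit_affine(pts, pts)
  expect_equal(ident$matrix, affine_transform()$matrix, tolerance = 1e-10)
  expect_lt(ident$rms, 1e-10)

  # well-separated grid, as mutual-NN matching assumes displacements small
  # relative to the point spacing
  grid <- tidyr::expand_grid(x = seq(10, 190, 20), y = seq(10, 190, 20))
  shift <- fit_affine(grid, dplyr::mutate(grid, x = x + 5, y = y - 3),
                      radius = 8)
  expect_equal(shift$matrix[, 3], c(5, -3), tolerance = 1e-9)
  expect_equal(shift$matrix[, 1:2], diag(2), tolerance = 1e-12)

  truth <- affine_transform(matrix(c(1.01, 0.02, -0.015, 0.99), 2, 2),
                            translation = c(4.3, -2.1))
  dst <- tibble::as_tibble(
    spotr:::apply_affine_points(truth, pts$x, pts$y))
  fit <- fit_affine(pts, dst, matched = TRUE)
  expect_equal(fit$matrix, truth$matrix, tolerance = 1e-6)
})

test_that("affine fitting rejects degenerate input", {
  line <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  expect_error(fit_affine(line, line), "collinear")
  two <- tibble::tibble(x = c(0, 1), y = c(0, 1))
  expect_error(fit_affine(two, two, matched = TRUE), "at least 3")
})

test_that("fit residual under coordinate jitter follows sqrt(2) * sigma", {
  sigma <- 0.2
  rms <- withr::with_seed(21, {
    pts <- tibble::tibble(x = runif(200, 0, 300), y = runif(200, 0, 300))
    dst <- dplyr::mutate(pts, x = x + rnorm(200, 0, sigma),
                         y = y + rnorm(200, 0, sigma))
    fit_affine(pts, dst, matched = TRUE)$rms
  })
  expect_lt(abs(rms - sigma * sqrt(2)), 0.35 * sigma * sqrt(2))
})

test_that("affine resampling honours its exactness contracts", {
  img <- withr::with_seed(5, matrix(runif(40 * 50), 40, 50))
  expect_identical(apply_transform(img, affine_transform()), img)

  sh <- apply_transform(img, affine_transform(translation = c(3, 2)))
  expect_equal(sh[(1 + 2):40, (1 + 3):50], img[1:(40 - 2), 1:(50 - 3)])
  expect_true(all(sh[1:2, ] == 0) && all(sh[, 1:3] == 0))

  # smooth image: warp there and back stays within 1% of the dynamic range
  sm <- outer(sin((0:63) / 10), cos((0:63) / 12)) + 2
  tf <- affine_transform(matrix(c(cos(0.05), sin(0.05),
                                  -sin(0.05), cos(0.05)), 2, 2),
                         translation = c(1.3, -0.7))
  back <- apply_transform(apply_transform(sm, tf), spotr:::invert_affine(tf))
  interior <- abs(back - sm)[10:54, 10:54]
  expect_lt(max(interior), 0.01 * diff(range(sm)))
})

test_that("rotation approximately preserves total interior intensity", {
  img <- matrix(0, 64, 64)
  img[25:40, 25:40] <- 1
  rot <- affine_transform(matrix(c(cos(0.2), sin(0.2),
                                   -sin(0.2), cos(0.2)), 2, 2),
                          translation = c(32 - 32 * cos(0.2) + 32 * sin(0.2),
                                          32 - 32 * sin(0.2) - 32 * cos(0.2)))
  out <- apply_transform(img, rot)
  expect_lt(abs(sum(out) - sum(img)) / sum(img), 0.01)
})

test_that("flat-field estimation recovers smooth envelopes", {
  expect_equal(unclass(estimate_flatfield(matrix(7, 32, 32))),
               matrix(1, 32, 32), tolerance = 1e-12)
  expect_error(estimate_flatfield(matrix(0, 8, 8)), "no signal")

  # replicate inputs equal the flat-field of their mean
  a <- withr::with_seed(2, matrix(runif(32 * 32, 1, 2), 32, 32))
  b <- withr::with_seed(3, matrix(runif(32 * 32, 1, 2), 32, 32))
  expect_equal(unclass(estimate_flatfield(list(a, b))),
               unclass(estimate_flatfield((a + b) / 2)), tolerance = 1e-12)

  # Gaussian illumination envelope sampled by a dense jittered bead lawn
  n <- 128
  xs <- 0:(n - 1)
  env <- outer(exp(-(xs - 70)^2 / (2 * n^2)), exp(-(xs - 50)^2 / (2 * n^2)))
  beads <- withr::with_seed(9, {
    img <- matrix(0, n, n)
    centers <- expand.grid(x = seq(2, n - 3, by = 2), y = seq(2, n - 3, by = 2))
    jx <- runif(nrow(centers), -0.5, 0.5)
    jy <- runif(nrow(centers), -0.5, 0.5)
    for (i in seq_len(nrow(centers))) {
      img <- img + oracle_spot(c(n, n), centers$x[i] + jx[i],
                               centers$y[i] + jy[i], sigma = 1.5, amp = 100)
    }
    img
  })
  ff <- estimate_flatfield(beads * env)
  truth <- env / mean(env)
  # interior: the bead lawn itself thins out at the very border
  rel <- (ff / truth - 1)[9:(n - 8), 9:(n - 8)]
  expect_lt(sqrt(mean(rel^2)), 0.02)
})

test_that("flat-field correction divides all six frames and enforces unit mean", {
  cfg <- spot_config(image_shape = c(32, 32), channels = "green")
  em <- dipole_emitters(x = 1000, y = 1000)
  stk <- render_spot_stack(em, cfg)
  unit <- estimate_flatfield(matrix(5, 32, 32))
  expect_equal(correct_flatfield(stk, unit)$frames, stk$frames,
               tolerance = 1e-12)
  expect_error(correct_flatfield(stk, matrix(2, 32, 32)), "unit mean")
  expect_error(correct_flatfield(stk, unclass(unit)[1:16, 1:16, drop = FALSE]),
               "shape")

  # correction commutes with a global gain
  ff <- estimate_flatfield(
    outer(seq(0.5, 1.5, length.out = 32), seq(0.8, 1.2, length.out = 32)))
  scaled <- spotr:::map_frames(stk, function(fr) fr * 3)
  expect_equal(correct_flatfield(scaled, ff)$frames,
               spotr:::map_frames(correct_flatfield(stk, ff),
                                  function(fr) fr * 3)$frames,
               tolerance = 1e-12)
})

test_that("a rendered illumination envelope is flattened by its estimate", {
  cfg <- plane_config(shape = c(64, 64))
  em <- plane_emitters(cfg, z = 0, brightness = 100)
  stk <- render_spot_stack(em, cfg)
  env <- outer(seq(0.6, 1.4, length.out = 64), seq(0.8, 1.2, length.out = 64))
  shaded <- spotr:::map_frames(stk, function(fr) fr * env)
  ff <- estimate_flatfield(uniform_image(shaded, 1, 1), sigma = 8)
  fixed <- correct_flatfield(shaded, ff)
  u <- uniform_image(fixed, 1, 1)
  interior <- u[17:48, 17:48]
  expect_lt(stats::sd(interior) / mean(interior), 0.02)
})
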