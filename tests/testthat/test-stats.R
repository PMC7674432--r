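test_that("polyline sampling measures bands with masks", {
  const <- matrix(7, 32, 32)
  line <- tibble::tibble(x = c(2, 20), y = c(5, 5))
  pm <- sample_polyline(const, line, halfwidth = 1)
  expect_equal(pm$mean, 7)
  expect_equal(pm$sd, 0)

  # linear x-gradient: the band mean equals the midpoint value
  grad <- matrix(rep(0:31, each = 32), 32, 32)
  pm2 <- sample_polyline(grad, tibble::tibble(x = c(4, 24), y = c(10, 10)))
  expect_lt(abs(pm2$mean - 14), 1)

  mask <- matrix(FALSE, 32, 32)
  expect_error(sample_polyline(const, line, mask = mask), "masked")
  expect_error(sample_polyline(const, tibble::tibble(x = 3, y = 3)), "two vertices")
})

test_that("repeat acceptance implements the inclusive 15% fluctuation rule", {
  ok <- repeat_acceptance(c(1, 1, 1))
  expect_true(ok$accepted)
  expect_equal(ok$fluctuation, 0)

  rej <- repeat_acceptance(c(1.0, 1.0, 1.2))
  expect_false(rej$accepted)
  expect_equal(rej$fluctuation, 0.1875, tolerance = 1e-12)

  # boundary case: exactly 15% is accepted (inclusive convention)
  edge <- repeat_acceptance(c(0.925, 1.075)) # (max-min)/mean = 0.15/1 = 0.15
  expect_equal(edge$fluctuation, 0.15, tolerance = 1e-12)
  expect_true(edge$accepted)

  # scale invariance of the decision
  vals <- c(0.9, 1.0, 1.02)
  expect_equal(repeat_acceptance(vals * 3)$fluctuation,
               repeat_acceptance(vals)$fluctuation, tolerance = 1e-12)
  expect_error(repeat_acceptance(1), "at least two")
  expect_error(repeat_acceptance(c(-1, 1)), "zero")
})

test_that("group ellipses summarize point clouds correctly", {
  pts <- tibble::tibble(ratio = c(1, 2, 3, 2), depth = c(0.2, 0.5, 0.3, 0.4))
  ge <- fit_group_ellipse(pts, "er")
  expect_equal(unname(ge$mean), c(2, 0.35))
  expect_equal(unname(ge$cov), unname(stats::cov(cbind(pts$ratio, pts$depth))))
  expect_error(fit_group_ellipse(pts[1:2, ]), "three")
  expect_error(fit_group_ellipse(
    tibble::tibble(ratio = 1:5, depth = 2 * (1:5))), "collinear")

  iso <- withr::with_seed(10, tibble::tibble(ratio = rnorm(1e4, 1, 0.1),
                                             depth = rnorm(1e4, 0.5, 0.1)))
  ev <- eigen(fit_group_ellipse(iso)$cov)$values
  expect_lt(abs(sqrt(ev[1] / ev[2]) - 1), 0.05)
})

test_that("ellipse fitting is equivariant under axis-wise rescaling", {
  pts <- withr::with_seed(11, tibble::tibble(ratio = rnorm(50, 1.2, 0.15),
                                             depth = rnorm(50, 0.6, 0.05)))
  ge <- fit_group_ellipse(pts)
  ge2 <- fit_group_ellipse(
    dplyr::mutate(pts, ratio = 2 * ratio + 1, depth = 0.5 * depth - 0.2))
  expect_equal(unname(ge2$mean), unname(c(2 * ge$mean[1] + 1,
                                          0.5 * ge$mean[2] - 0.2)),
               tolerance = 1e-12)
  s <- diag(c(2, 0.5))
  expect_equal(unname(ge2$cov), unname(s %*% ge$cov %*% s), tolerance = 1e-12)
  # classification is invariant under the same rescaling
  p <- c(1.3, 0.62)
  expect_equal(
    classify_compartment(c(2 * p[1] + 1, 0.5 * p[2] - 0.2), list(ge2)),
    classify_compartment(p, list(ge))
  )
})

test_that("exclusive-ellipse classification distinguishes the three outcomes", {
  mk <- function(cx, cy, label) {
    withr::with_seed(12, fit_group_ellipse(
      tibble::tibble(ratio = rnorm(200, cx, 0.05),
                     depth = rnorm(200, cy, 0.05)), label))
  }
  e1 <- mk(1.0, 0.3, "lysosome")
  e2 <- mk(1.05, 0.33, "golgi")   # overlaps e1
  e3 <- mk(2.0, 0.8, "nuclear")
  expect_equal(classify_compartment(c(2.0, 0.8), list(e1, e2, e3)), "nuclear")
  expect_equal(classify_compartment(c(1.02, 0.315), list(e1, e2, e3)),
               "ambiguous")
  expect_equal(classify_compartment(c(5, 5), list(e1, e2, e3)), "unassigned")
  # order invariance
  for (perm in list(c(3, 1, 2), c(2, 3, 1))) {
    expect_equal(classify_compartment(c(2.0, 0.8), list(e1, e2, e3)[perm]),
                 "nuclear")
  }
})

test_that("ellipse contours sit at the requested Mahalanobis radius", {
  pts <- withr::with_seed(13, tibble::tibble(ratio = rnorm(500, 0, 1),
                                             depth = rnorm(500, 0, 2)))
  ge <- fit_group_ellipse(pts)
  for (r in c(1, 2)) {
    cont <- ellipse_contour(ge, r)
    d2 <- apply(cont, 1, function(p) spotr:::mahalanobis2(p, ge))
    expect_equal(unname(d2), rep(r^2, nrow(cont)), tolerance = 1e-9)
  }
})
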