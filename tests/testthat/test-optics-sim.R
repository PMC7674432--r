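test_that("excitation response covers the dipole limits and is pi-periodic", {
  expect_equal(excitation_response(0.7, 0.7, 1), 2)
  expect_equal(excitation_response(1.3, 0.2, 0), 1)
  expect_equal(excitation_response(pi / 2, 0, 1), 0)
  th <- seq(0, pi, length.out = 13)
  expect_equal(excitation_response(th + pi, 0.3, 0.8),
               excitation_response(th, 0.3, 0.8))
  expect_equal(excitation_response(th, 0.3 + pi, 0.8),
               excitation_response(th, 0.3, 0.8))
  # three equally spaced polarizations collect an orientation-independent total
  for (phi in c(0, 0.4, 1.1, 2.9)) {
    expect_equal(sum(excitation_response(c(0, pi / 3, 2 * pi / 3), phi, 1)), 3)
  }
  expect_error(excitation_response(0, 0, 1.2), "\\[0, 1\\]")
})

test_that("psf weight matches its closed form and decreases monotonically", {
  cfg <- spot_config()
  expect_equal(psf_weight(0, 0, 0, cfg), 1)
  expect_equal(psf_weight(230, 0, 0, cfg), 2^-4)
  # product of independently evaluated lateral and axial factors
  lat <- exp(-4 * log(2) * (50 / 230)^2)
  axi <- exp(-4 * log(2) * (300 / 670)^2)
  expect_equal(psf_weight(50, 0, 300, cfg), lat * axi, tolerance = 1e-12)
  d <- seq(0, 800, by = 50)
  expect_true(all(diff(psf_weight(d, 0, 0, cfg)) < 0))
  expect_true(all(diff(psf_weight(0, d, 0, cfg)) < 0))
  expect_true(all(diff(psf_weight(0, 0, d, cfg)) < 0))
})

test_that("emitter table validation enforces the physical invariants", {
  em <- dipole_emitters(x = 0, y = 0, orientation = 4)
  expect_true(em$orientation >= 0 && em$orientation < pi)
  expect_error(dipole_emitters(x = 0, y = 0, emission_ratio = 0), "> 0")
  expect_error(dipole_emitters(x = 0, y = 0, wobble = 1.2), "\\[0, 1\\]")
  expect_error(dipole_emitters(x = numeric(0), y = numeric(0)), "empty")
})

test_that("rendering is linear in the emitter set", {
  cfg <- spot_config(image_shape = c(48, 48), background = 3)
  e1 <- dipole_emitters(x = 900, y = 1100, orientation = 0.4, wobble = 0.7)
  e2 <- dipole_emitters(x = 1800, y = 1500, emission_ratio = 0.5,
                        orientation = 2, wobble = 0.2)
  both <- rbind(e1, e2)
  s1 <- render_spot_stack(e1, cfg)
  s2 <- render_spot_stack(e2, cfg)
  s12 <- render_spot_stack(both, cfg)
  for (k in 1:3) {
    for (p in 1:2) {
      expect_equal(spot_frame(s12, k, p, "green"),
                   spot_frame(s1, k, p, "green") +
                     spot_frame(s2, k, p, "green") - cfg$background,
                   tolerance = 1e-12)
    }
  }
})

test_that("averaging the pi-shifted phase pair removes the pattern exactly", {
  cfg <- spot_config(image_shape = c(48, 48))
  em <- dipole_emitters(x = 1430, y = 1430, orientation = 0.9, wobble = 0.6)
  stk <- render_spot_stack(em, cfg)
  # after dividing out the polarization response, the phase-averaged images
  # of the three directions coincide: no pattern survives the pi average
  exc <- excitation_angles(cfg)
  r <- excitation_response(exc, em$orientation, em$wobble)
  u1 <- uniform_image(stk, 1, "green") / r[1]
  u2 <- uniform_image(stk, 2, "green") / r[2]
  u3 <- uniform_image(stk, 3, "green") / r[3]
  expect_equal(u2, u1, tolerance = 1e-12)
  expect_equal(u3, u1, tolerance = 1e-12)
})

test_that("a free rotor responds identically in all pattern directions", {
  cfg <- spot_config(image_shape = c(48, 48))
  # at the origin every pattern has the same phase, so whole frames agree there
  em <- dipole_emitters(x = 0, y = 0, wobble = 0)
  stk <- render_spot_stack(em, cfg)
  v <- sapply(1:3, function(k) spot_frame(stk, k, 1, "green")[1, 1])
  expect_equal(v[2], v[1], tolerance = 1e-12)
  expect_equal(v[3], v[1], tolerance = 1e-12)
})

test_that("an emitter on a pattern crest vanishes in the pi-shifted frame", {
  cfg <- spot_config(image_shape = c(48, 64), background = 0)
  # pixel x = 46 sits exactly on a crest of direction 1:
  # 46 px * 65 nm = 2990 nm = 13 pattern periods
  em <- dipole_emitters(x = 46 * cfg$pixel_size, y = 1430, wobble = 0)
  stk <- render_spot_stack(em, cfg)
  px <- round(em$x / cfg$pixel_size)
  py <- round(em$y / cfg$pixel_size)
  v0 <- spot_frame(stk, 1, 1, "green")[py + 1, px + 1]
  vpi <- spot_frame(stk, 1, 2, "green")[py + 1, px + 1]
  # s = 1 + cos(pi) = 0 at the crest
  expect_gt(v0, 100)
  expect_lt(vpi / v0, 1e-12)
})

test_that("a warning is raised when no emitter is in view", {
  cfg <- spot_config(image_shape = c(32, 32), background = 2)
  em <- dipole_emitters(x = 1e6, y = 1e6)
  expect_warning(stk <- render_spot_stack(em, cfg), "field of view")
  expect_equal(spot_frame(stk, 1, 1, "green"),
               matrix(2, 32, 32))
})

test_that("noise is seeded, reproducible, and has the stated moments", {
  cfg <- spot_config(image_shape = c(100, 100), channels = "green",
                     read_noise_sd = 1)
  const <- matrix(100, 100, 100)
  frames <- lapply(1:3, function(k) lapply(1:2, function(p) list(green = const)))
  stk <- as_spot_stack(frames, cfg)
  expect_error(add_noise(stk), "seed")
  n1 <- add_noise(stk, seed = 11)
  n2 <- add_noise(stk, seed = 11)
  n3 <- add_noise(stk, seed = 12)
  expect_identical(n1$frames, n2$frames)
  expect_false(identical(n1$frames, n3$frames))
  # sample mean within 3 sigma/sqrt(N) of the expectation (var = 100 + 1)
  f <- spot_frame(n1, 1, 1, "green")
  expect_lt(abs(mean(f) - 100), 3 * sqrt(101) / sqrt(length(f)))
  # Poisson(0) with zero read noise stays exactly zero
  cfg0 <- spot_config(image_shape = c(16, 16), channels = "green",
                      read_noise_sd = 0)
  z <- matrix(0, 16, 16)
  stk0 <- as_spot_stack(lapply(1:3, function(k) {
    lapply(1:2, function(p) list(green = z))
  }), cfg0)
  expect_equal(spot_frame(add_noise(stk0, 5), 1, 1, "green"), z)
})

test_that("bead fields honour the requested transform", {
  ident <- affine_transform()
  bf <- generate_bead_field(10, ident, seed = 3)
  expect_equal(bf$beads$x_a, bf$beads$x_b)
  expect_equal(bf$image_a, bf$image_b)
  tr <- affine_transform(translation = c(5, -3))
  bf2 <- generate_bead_field(10, tr, seed = 3)
  expect_equal(bf2$beads$x_b - bf2$beads$x_a, rep(5, 10))
  expect_equal(bf2$beads$y_b - bf2$beads$y_a, rep(-3, 10))
  far <- affine_transform(translation = c(1e5, 0))
  expect_error(generate_bead_field(5, far, seed = 1), "outside the frame")
})
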