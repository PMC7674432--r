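hp <- hilo_params(pattern_period_px = 6)

test_that("hilo rejects smooth unmodulated background", {
  xs <- 0:63
  blur <- outer(exp(-(xs - 32)^2 / (2 * 30^2)), exp(-(xs - 32)^2 / (2 * 30^2)))
  out <- hilo_pair(blur, blur, hp)
  expect_lt(max(out), 0.02 * mean(blur))
})

test_that("hilo formula limits hold: alpha = 0, zeros, swap, homogeneity", {
  i0 <- withr::with_seed(1, matrix(runif(64 * 64, 0, 10), 64, 64))
  ipi <- withr::with_seed(2, matrix(runif(64 * 64, 0, 10), 64, 64))
  hp0 <- hilo_params(alpha = 0, cutoff = hp$cutoff)
  u <- (i0 + ipi) / 2
  hi <- u - spotr:::lowpass_gaussian(u, hp$cutoff)
  expect_equal(as.vector(hilo_pair(i0, ipi, hp0)), as.vector(pmax(hi, 0)),
               tolerance = 1e-12)

  z <- matrix(0, 16, 16)
  expect_equal(as.vector(hilo_pair(z, z, hp)), as.vector(z))

  a <- hilo_pair(i0, ipi, hp)
  b <- hilo_pair(ipi, i0, hp)
  expect_equal(as.vector(a), as.vector(b), tolerance = 1e-12)

  c3 <- hilo_pair(3 * i0, 3 * ipi, hp)
  expect_equal(as.vector(c3), 3 * as.vector(a), tolerance = 1e-10)

  expect_error(hilo_pair(i0, ipi[1:32, ], hp), "same shape")
  expect_true(all(a >= 0))
})

test_that("a fully modulated in-focus uniform field keeps its mean", {
  xs <- 0:127
  pat <- matrix(cos(2 * pi * xs / 6), 128, 128, byrow = TRUE)
  out <- hilo_pair(1 + pat, 1 - pat, hilo_params(pattern_period_px = 6))
  expect_lt(abs(mean(out) - 1), 0.25)
  expect_true(isTRUE(attr(out, "eta_fallback"))) # flat field: Hi band empty
})

test_that("hilo suppresses a defocused plane but keeps the in-focus plane", {
  cfg <- plane_config()
  dz <- 2 * cfg$fwhm_axial
  stk_focus <- render_spot_stack(plane_emitters(cfg, z = 0), cfg)
  stk_defoc <- render_spot_stack(plane_emitters(cfg, z = dz), cfg)
  # wide-field (phase-averaged) means are comparable: energy conservation
  wf_focus <- interior_mean(uniform_image(stk_focus))
  wf_defoc <- interior_mean(uniform_image(stk_defoc))
  expect_lt(max(wf_focus / wf_defoc, wf_defoc / wf_focus), 2)
  # sectioning suppresses the defocused plane
  sec_focus <- interior_mean(section_stack(stk_focus)$images[[1]])
  sec_defoc <- interior_mean(section_stack(stk_defoc)$images[[1]])
  expect_lt(sec_defoc / sec_focus, 0.2)
})

test_that("spot intensity is the symmetric mean of three sections", {
  a <- matrix(1, 4, 4)
  expect_equal(spot_intensity(list(a, a, a)), a)
  expect_equal(spot_intensity(list(a * 0, a, a * 2)), a)
  imgs <- withr::with_seed(4, lapply(1:3, function(i) matrix(runif(16), 4, 4)))
  expect_equal(spot_intensity(imgs), spot_intensity(imgs[c(3, 1, 2)]))
  expect_error(spot_intensity(imgs[1:2]), "three")
})

test_that("the five-phase adapter synthesizes a valid pi pair", {
  a <- matrix(2, 8, 8)
  same <- sim5_to_pair(replicate(5, a, simplify = FALSE))
  expect_equal(same$uniform, same$i0)
  xs <- matrix(0:7, 8, 8, byrow = TRUE)
  five <- lapply(0:4, function(j) 1 + 0.8 * cos(2 * pi * xs / 4 + 2 * pi * j / 5))
  adapted <- sim5_to_pair(five)
  expect_equal(adapted$uniform, matrix(1, 8, 8), tolerance = 1e-12)
  expect_equal((adapted$i0 + adapted$ipi) / 2, adapted$uniform,
               tolerance = 1e-12)
  expect_error(sim5_to_pair(five[1:4]), "five")
})

test_that("the five-phase adapter sections like the two-phase path", {
  cfg <- plane_config()
  dz <- 2 * cfg$fwhm_axial
  mk5 <- function(z) {
    base <- plane_emitters(cfg, z = z)
    lapply(2 * pi * (0:4) / 5, function(ph) {
      cfg5 <- spot_config(
        fwhm_lateral = cfg$fwhm_lateral, fwhm_axial = cfg$fwhm_axial,
        pixel_size = cfg$pixel_size, pattern_period = cfg$pattern_period,
        pattern_phases = c(ph, ph + pi), channels = "green",
        background = 0, read_noise_sd = 0, image_shape = cfg$image_shape
      )
      spot_frame(render_spot_stack(base, cfg5), 1, 1, 1)
    })
  }
  params <- hilo_params(pattern_period_px = cfg$pattern_period / cfg$pixel_size)
  sec <- function(z) {
    pair <- sim5_to_pair(mk5(z))
    interior_mean(hilo_pair(pair$i0, pair$ipi, params))
  }
  expect_lt(sec(dz) / sec(0), 0.2)
})
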