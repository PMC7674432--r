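# Shared fixtures, all generated in code.

# A single-channel configuration for sectioning experiments: the stripe
# period is ~2x the pattern default so the detected pattern contrast is
# appreciable after lateral PSF blur.
plane_config <- function(shape = c(48, 48), period = 390) {
  spot_config(
    fwhm_lateral = 230, fwhm_axial = 670, pixel_size = 65,
    pattern_period = period, channels = "green",
    background = 0, read_noise_sd = 0, image_shape = shape
  )
}

# A laterally uniform thin fluorescent plane at defocus z: one emitter per
# pixel. An extended out-of-focus layer conserves detected energy, so the
# per-emitter brightness is scaled by the inverse axial peak weight.
plane_emitters <- function(config, z = 0, brightness = 1000) {
  shape <- config$image_shape
  px <- config$pixel_size
  g <- expand.grid(x = (0:(shape[2] - 1)) * px, y = (0:(shape[1] - 1)) * px)
  b <- brightness / psf_weight(0, 0, z, config)
  dipole_emitters(x = g$x, y = g$y, z = z, brightness = b, wobble = 0)
}

# Interior mean, away from borders and wrap artefacts.
interior_mean <- function(img, margin = 8) {
  mean(img[(margin + 1):(nrow(img) - margin), (margin + 1):(ncol(img) - margin)])
}

# Phase-averaged (uniform illumination) image of one direction/channel.
uniform_image <- function(stack, k = 1, channel = 1) {
  (spot_frame(stack, k, 1, channel) + spot_frame(stack, k, 2, channel)) / 2
}

# Render an isolated-emitter scene on a grid of pixel centers with randomized
# per-emitter properties; returns list(stack, emitters, px, py).
grid_scene <- function(n_x = 6, n_y = 4, spacing = 48, seed = 42,
                       channels = c("red", "green"),
                       channel_split = "equal_total",
                       brightness = 1e4) {
  shape <- c((n_y + 1) * spacing, (n_x + 1) * spacing)
  cfg <- spot_config(image_shape = shape, channels = channels,
                     channel_split = channel_split,
                     background = 0, read_noise_sd = 0)
  n <- n_x * n_y
  withr::with_seed(seed, {
    px <- rep(seq_len(n_x) * spacing, times = n_y)
    py <- rep(seq_len(n_y) * spacing, each = n_x)
    em <- dipole_emitters(
      x = px * cfg$pixel_size, y = py * cfg$pixel_size, z = 0,
      brightness = brightness,
      emission_ratio = runif(n, 0.3, 1.5),
      orientation = runif(n, 0, pi),
      wobble = runif(n, 0, 1)
    )
    list(stack = render_spot_stack(em, cfg), emitters = em,
         px = px, py = py, config = cfg)
  })
}

# Independent single-pixel oracle for the three-angle cosine fit: linear
# least squares on the design [1, cos 2theta, sin 2theta].
lsq_cosine_fit <- function(y, theta) {
  X <- cbind(1, cos(2 * theta), sin(2 * theta))
  cf <- solve(crossprod(X), crossprod(X, y))
  list(a = cf[1], m = sqrt(cf[2]^2 + cf[3]^2) / cf[1],
       phi = (atan2(cf[3], cf[2]) / 2) %% pi)
}

# Unit-peak Gaussian spot rendered directly from its closed form (oracle,
# independent of the package's renderer).
oracle_spot <- function(shape, x0, y0, sigma, amp = 1) {
  xs <- 0:(shape[2] - 1)
  ys <- 0:(shape[1] - 1)
  amp * outer(exp(-(ys - y0)^2 / (2 * sigma^2)),
              exp(-(xs - x0)^2 / (2 * sigma^2)))
}
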