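#' @keywords internal
#' Evaluate a unit-peak lateral Gaussian spot on a pixel window.
#' Returns list(rows, cols, patch) in 1-based matrix indices, or NULL if the
#' window misses the frame. Positions in pixel units, 0-based centers.
spot_patch <- function(x_px, y_px, sigma_px, shape, radius) {
  ny <- shape[1]
  nx <- shape[2]
  cx <- round(x_px)
  cy <- round(y_px)
  cols <- max(0, cx - radius):min(nx - 1, cx + radius)
  rows <- max(0, cy - radius):min(ny - 1, cy + radius)
  if (cx + radius < 0 || cx - radius > nx - 1 ||
      cy + radius < 0 || cy - radius > ny - 1) {
    return(NULL)
  }
  gx <- exp(-(cols - x_px)^2 / (2 * sigma_px^2))
  gy <- exp(-(rows - y_px)^2 / (2 * sigma_px^2))
  list(rows = rows + 1L, cols = cols + 1L, patch = outer(gy, gx))
}

#' Render a six-frame SPOT acquisition of dipole emitters
#'
#' Forward model of SPOT structured-illumination acquisition: for every
#' pattern direction \eqn{k}, phase \eqn{p} and spectral channel \eqn{c},
#' the noiseless expected image is
#' \deqn{I_{kpc}(x) = b + \sum_e B_e\, w_{psf}(x - x_e)\,
#'   [1 + M(z_e)\cos(\vec k_k\cdot\vec x + p)]\,
#'   [1 + m_e\cos(2(\theta_k^{exc} - \phi_e))]\, g_c\, s_c(\rho_e),}
#' where \eqn{w_{psf}} is the separable Gaussian detection weight,
#' \eqn{M(z) = \exp(-4\ln 2\, z^2/\mathrm{FWHM}_{ax}^2)} the axial envelope
#' of the illumination pattern contrast (the pattern is projected at the
#' focal plane and washes out with defocus — the mechanism that gives HiLo
#' its optical sectioning), \eqn{\theta_k^{exc}} the excitation polarization
#' of direction \eqn{k}, \eqn{g_c} the channel gain and \eqn{s_c(\rho)} the
#' channel-split weight (see [spot_config()]).
#'
#' The pattern phase \eqn{\vec k_k\cdot\vec x} is evaluated at the detection
#' pixel \eqn{x} (the smooth-sample approximation, under which blur and
#' modulation commute); the two conventions agree after phase averaging, and
#' this one keeps the rectified-cosine HiLo demodulation exact for sparse
#' scenes as well as extended ones (see the methods vignette).
#'
#' @param emitters A [dipole_emitters()] table.
#' @param config A [spot_config()].
#' @return A `spot_stack`: nested frames `[[direction]][[phase]][[channel]]`
#'   of expected photon counts, plus the configuration and provenance.
#' @examples
#' em <- dipole_emitters(x = 2080, y = 2080)
#' stk <- render_spot_stack(em, spot_config(image_shape = c(64, 64)))
#' stk
#' @export
render_spot_stack <- function(emitters, config) {
  stopifnot(inherits(config, "spot_config"))
  emitters <- validate_emitters(emitters)
  shape <- config$image_shape
  px <- config$pixel_size
  sigma_px <- sigma_lateral_px(config)
  radius <- as.integer(ceiling(5 * sigma_px) + 1L)
  l2 <- 4 * log(2)
  exc <- excitation_angles(config)
  kmag <- 2 * pi / config$pattern_period

  # pattern phase maps, evaluated on the pixel grid (nm coordinates)
  xs <- (0:(shape[2] - 1)) * px
  ys <- (0:(shape[1] - 1)) * px
  pattern_cos <- lapply(1:3, function(k) {
    theta <- config$pattern_angles[k]
    karg <- outer(sin(theta) * ys, cos(theta) * xs, "+") * kmag
    lapply(config$pattern_phases, function(ph) cos(karg + ph))
  })

  frames <- empty_frames(config)
  hit <- FALSE
  for (e in seq_len(nrow(emitters))) {
    x_px <- emitters$x[e] / px
    y_px <- emitters$y[e] / px
    sp <- spot_patch(x_px, y_px, sigma_px, shape, radius)
    if (is.null(sp)) next
    hit <- TRUE
    axial <- exp(-l2 * emitters$z[e]^2 / config$fwhm_axial^2)
    contrast <- axial # same Gaussian envelope for pattern modulation
    split <- channel_split_weights(emitters$emission_ratio[e], config)
    base <- emitters$brightness[e] * axial * sp$patch
    for (k in 1:3) {
      r_pol <- excitation_response(exc[k], emitters$orientation[e],
                                   emitters$wobble[e])
      for (p in 1:2) {
        s_kp <- 1 + contrast * pattern_cos[[k]][[p]][sp$rows, sp$cols]
        for (c in seq_along(config$channels)) {
          ch <- config$channels[c]
          amp <- r_pol * split[[ch]] * config$channel_gains[[ch]]
          if (amp == 0) next
          frames[[k]][[p]][[c]][sp$rows, sp$cols] <-
            frames[[k]][[p]][[c]][sp$rows, sp$cols] + amp * base * s_kp
        }
      }
    }
  }
  if (!hit) {
    warning("no emitter falls inside the field of view; background-only stack",
            call. = FALSE)
  }
  if (config$background != 0) {
    frames <- purrr::map(frames, function(d) {
      purrr::map(d, function(p) purrr::map(p, `+`, config$background))
    })
  }
  new_spot_stack(frames, config, meta = list(emitters = emitters))
}

#' @keywords internal
empty_frames <- function(config) {
  shape <- config$image_shape
  zero <- matrix(0, shape[1], shape[2])
  phase_names <- paste0("phase", seq_along(config$pattern_phases))
  lapply(1:3, function(k) {
    stats::setNames(
      lapply(seq_along(config$pattern_phases), function(p) {
        stats::setNames(
          lapply(config$channels, function(ch) zero),
          config$channels
        )
      }),
      phase_names
    )
  })
}

#' @keywords internal
new_spot_stack <- function(frames, config, meta = list()) {
  structure(list(frames = frames, config = config, meta = meta),
            class = "spot_stack")
}

#' Extract one raw frame from a SPOT stack
#'
#' @param stack A `spot_stack`.
#' @param direction Pattern direction index (1..3).
#' @param phase Phase index (1 = first phase, 2 = pi-shifted).
#' @param channel Channel label or index.
#' @return A numeric matrix.
#' @export
spot_frame <- function(stack, direction, phase, channel = 1) {
  stopifnot(inherits(stack, "spot_stack"),
            direction %in% 1:3, phase %in% 1:2)
  stack$frames[[direction]][[phase]][[channel]]
}

#' @export
print.spot_stack <- function(x, ...) {
  sh <- dim(x$frames[[1]][[1]][[1]])
  cat(sprintf(
    "<spot_stack> %d x %d px, 3 directions x %d phases x %d channel(s) [%s]\n",
    sh[1], sh[2], length(x$frames[[1]]), length(x$config$channels),
    paste(x$config$channels, collapse = ", ")
  ))
  if (!is.null(x$meta$emitters)) {
    cat(sprintf("  rendered from %d emitter(s)\n", nrow(x$meta$emitters)))
  }
  if (!is.null(x$meta$seed)) cat(sprintf("  noise seed: %d\n", x$meta$seed))
  invisible(x)
}

#' Map a function over every frame of a stack
#' @keywords internal
map_frames <- function(stack, f) {
  stack$frames <- lapply(stack$frames, function(d) {
    lapply(d, function(p) lapply(p, f))
  })
  stack
}

#' Apply Poisson shot noise and Gaussian read noise to a stack
#'
#' Pixel values of the input are treated as expected photon counts; the
#' output draws Poisson shot noise and adds zero-mean Gaussian read noise of
#' standard deviation `config$read_noise_sd`. Negative pixels are possible
#' after read noise. A seed is mandatory: noisy stacks are reproducible by
#' construction.
#'
#' @param stack A `spot_stack` with nonnegative frames.
#' @param seed Integer seed.
#' @return A `spot_stack` with noisy frames; the seed is recorded in the
#'   stack's metadata.
#' @export
add_noise <- function(stack, seed) {
  stopifnot(inherits(stack, "spot_stack"))
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("`seed` is required: noise must be reproducible", call. = FALSE)
  }
  sd_read <- stack$config$read_noise_sd
  out <- withr::with_seed(as.integer(seed), {
    map_frames(stack, function(fr) {
      if (any(fr < 0)) stop("expected-photon frames must be nonnegative",
                            call. = FALSE)
      n <- length(fr)
      noisy <- stats::rpois(n, lambda = fr)
      if (sd_read > 0) noisy <- noisy + stats::rnorm(n, 0, sd_read)
      matrix(noisy, nrow(fr), ncol(fr))
    })
  })
  out$meta$seed <- as.integer(seed)
  out
}

#' Simulate a two-channel fiducial bead field for registration
#'
#' Renders the same random bead constellation in a reference channel and in a
#' second channel displaced by a known affine transform, together with the
#' ground-truth coordinates — the synthetic counterpart of imaging an
#' alignment slide of sub-diffraction beads.
#'
#' @param n Number of beads (>= 3).
#' @param transform A 2x3 affine matrix (pixel units) mapping channel-A
#'   coordinates to channel-B coordinates; see [affine_transform()].
#' @param seed Integer seed for the bead positions.
#' @param config A [spot_config()]; supplies image shape and PSF width.
#' @param brightness Peak photons per bead.
#' @param min_distance Minimum pairwise bead distance (px), enforced by
#'   rejection sampling so localizations stay isolated.
#' @param margin Keep-out border (px).
#' @return A list with `image_a`, `image_b` (matrices) and `beads`, a tibble
#'   of ground-truth coordinates `x_a, y_a, x_b, y_b` (px, 0-based centers).
#' @export
generate_bead_field <- function(n, transform, seed,
                                config = spot_config(image_shape = c(256, 256)),
                                brightness = 5000,
                                min_distance = 12, margin = 12) {
  stopifnot(n >= 3)
  transform <- as_affine(transform)
  shape <- config$image_shape
  pts <- withr::with_seed(as.integer(seed), {
    acc <- matrix(numeric(0), ncol = 2)
    tries <- 0
    while (nrow(acc) < n && tries < 20000) {
      cand <- c(stats::runif(1, margin, shape[2] - 1 - margin),
                stats::runif(1, margin, shape[1] - 1 - margin))
      if (nrow(acc) == 0 ||
          min(sqrt((acc[, 1] - cand[1])^2 + (acc[, 2] - cand[2])^2)) >=
            min_distance) {
        acc <- rbind(acc, cand)
      }
      tries <- tries + 1
    }
    acc
  })
  if (nrow(pts) < n) {
    stop("could not place beads at the requested density", call. = FALSE)
  }
  dimnames(pts) <- NULL
  pts_b <- apply_affine_points(transform, pts[, 1], pts[, 2])
  inside_b <- pts_b$x > -1 & pts_b$x < shape[2] &
    pts_b$y > -1 & pts_b$y < shape[1]
  if (!any(inside_b)) {
    stop("transform maps all beads outside the frame", call. = FALSE)
  }
  sigma_px <- sigma_lateral_px(config)
  render1 <- function(xs, ys) {
    img <- matrix(0, shape[1], shape[2])
    radius <- as.integer(ceiling(5 * sigma_px) + 1L)
    for (i in seq_along(xs)) {
      sp <- spot_patch(xs[i], ys[i], sigma_px, shape, radius)
      if (is.null(sp)) next
      img[sp$rows, sp$cols] <- img[sp$rows, sp$cols] + brightness * sp$patch
    }
    img
  }
  list(
    image_a = render1(pts[, 1], pts[, 2]),
    image_b = render1(pts_b$x, pts_b$y),
    beads = tibble::tibble(x_a = pts[, 1], y_a = pts[, 2],
                           x_b = pts_b$x, y_b = pts_b$y)
  )
}
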