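#' HiLo sectioning parameters
#'
#' @param alpha Weight of the low-frequency (demodulated) band in the fusion
#'   `Hi + alpha * eta * Lo`. All experiments in the reference workflow use
#'   `alpha = 1`.
#' @param cutoff Spatial frequency (cycles/px) at which the Hi and Lo bands
#'   merge. Defaults to half the illumination pattern frequency when
#'   `pattern_period_px` is given.
#' @param pattern_period_px Illumination stripe period in pixels; used only
#'   to derive the default cutoff.
#' @return A `hilo_params` object.
#' @examples
#' hilo_params(pattern_period_px = 230 / 65)
#' @export
hilo_params <- function(alpha = 1, cutoff = NULL, pattern_period_px = NULL) {
  if (is.null(cutoff)) {
    if (is.null(pattern_period_px)) {
      stop("supply `cutoff` or `pattern_period_px`", call. = FALSE)
    }
    cutoff <- 1 / (2 * pattern_period_px)
  }
  stopifnot(alpha >= 0, cutoff > 0, cutoff < 0.5)
  structure(list(alpha = alpha, cutoff = cutoff), class = "hilo_params")
}

#' @keywords internal
#' Centered FFT frequency grids (cycles/px) for an ny x nx image.
freq_grid <- function(ny, nx) {
  fy <- (((0:(ny - 1)) + floor(ny / 2)) %% ny - floor(ny / 2)) / ny
  fx <- (((0:(nx - 1)) + floor(nx / 2)) %% nx - floor(nx / 2)) / nx
  list(fy = matrix(fy, ny, nx), fx = matrix(fx, ny, nx, byrow = TRUE))
}

#' @keywords internal
#' Exact 2x sinc (Fourier zero-padding) upsampling of a band-limited image.
#' Fine-grid sample 2n+1 coincides with original pixel n.
upsample2_fft <- function(x) {
  pad_map <- function(n, big) {
    k <- 0:(n - 1)
    kk <- ifelse(k <= n / 2, k, k - n)
    src <- seq_len(n)
    tgt <- (kk %% big) + 1
    w <- rep(1, n)
    if (n %% 2 == 0) { # split the Nyquist bin over +n/2 and -n/2
      nyq <- n / 2 + 1
      w[nyq] <- 0.5
      src <- c(src, nyq)
      tgt <- c(tgt, big - n / 2 + 1)
      w <- c(w, 0.5)
    }
    list(src = src, tgt = tgt, w = w)
  }
  ny <- nrow(x)
  nx <- ncol(x)
  f <- stats::fft(x)
  mr <- pad_map(ny, 2 * ny)
  mc <- pad_map(nx, 2 * nx)
  g1 <- matrix(0 + 0i, 2 * ny, nx)
  for (i in seq_along(mr$src)) {
    g1[mr$tgt[i], ] <- g1[mr$tgt[i], ] + mr$w[i] * f[mr$src[i], ]
  }
  g <- matrix(0 + 0i, 2 * ny, 2 * nx)
  for (j in seq_along(mc$src)) {
    g[, mc$tgt[j]] <- g[, mc$tgt[j]] + mc$w[j] * g1[, mc$src[j]]
  }
  Re(stats::fft(g, inverse = TRUE)) * 4 / length(g)
}

#' @keywords internal
#' Gaussian low-pass with half-amplitude at `cutoff` (sigma_f = cutoff/sqrt(2 ln 2)).
lowpass_gaussian <- function(img, cutoff) {
  g <- freq_grid(nrow(img), ncol(img))
  sigma_f <- cutoff / sqrt(2 * log(2))
  h <- exp(-(g$fx^2 + g$fy^2) / (2 * sigma_f^2))
  Re(stats::fft(stats::fft(img) * h, inverse = TRUE)) / length(img)
}

#' @keywords internal
#' Radially averaged FFT amplitudes of Hi and Lo in a +/-10% band around the
#' cutoff; eta equalizes the two band amplitudes. Falls back to 1 when either
#' band is empty (flat images), flagged in the result.
estimate_eta <- function(hi, lo, cutoff) {
  g <- freq_grid(nrow(hi), ncol(hi))
  r <- sqrt(g$fx^2 + g$fy^2)
  band <- r >= 0.9 * cutoff & r <= 1.1 * cutoff
  scale <- sum(abs(hi)) + sum(abs(lo))
  if (!any(band) || scale == 0) {
    return(list(eta = 1, fallback = TRUE))
  }
  a_hi <- mean(Mod(stats::fft(hi))[band])
  a_lo <- mean(Mod(stats::fft(lo))[band])
  if (a_hi < 1e-9 * scale || a_lo < 1e-9 * scale) {
    return(list(eta = 1, fallback = TRUE))
  }
  eta <- a_hi / a_lo
  # both bands carry half-amplitude transfer at the cutoff, so a sound merge
  # factor is O(1); extreme ratios mean one band holds no in-focus structure
  if (eta < 0.1 || eta > 10) {
    return(list(eta = 1, fallback = TRUE))
  }
  list(eta = eta, fallback = FALSE)
}

#' HiLo optical sectioning from a pi-shifted image pair
#'
#' Fuses the in-focus content of two structured-illumination images of the
#' same pattern direction whose pattern phases differ by `pi`:
#' the uniform image `U = (I0 + Ipi)/2` supplies the high-frequency in-focus
#' band `Hi = U - LP[U]`, and the difference `D = (I0 - Ipi)/2` — whose
#' modulation survives only in focus — supplies the low-frequency in-focus
#' band `Lo = LP[|D|] * pi/2` (the `pi/2` factor corrects the mean of the
#' rectified cosine). The output is `max(Hi + alpha * eta * Lo, 0)`, where
#' `eta` equalizes the radially averaged spectral amplitudes of the two bands
#' at the cutoff frequency.
#'
#' @param i0,ipi Same-shape matrices: the two pattern phases of one
#'   direction (order irrelevant).
#' @param params A [hilo_params()].
#' @return Sectioned image (matrix, nonnegative), with attributes `eta` and
#'   `eta_fallback`.
#' @export
hilo_pair <- function(i0, ipi, params) {
  stopifnot(is.matrix(i0), is.matrix(ipi), inherits(params, "hilo_params"))
  if (!all(dim(i0) == dim(ipi))) {
    stop("the two phase images must have the same shape", call. = FALSE)
  }
  u <- (i0 + ipi) / 2
  d <- (i0 - ipi) / 2
  # rectify on a 2x sinc-interpolated grid: |.| of the sampled carrier would
  # otherwise alias its 4th harmonic into the low-pass band for axis-aligned
  # pattern directions
  d_fine <- upsample2_fft(d)
  lo_fine <- lowpass_gaussian(abs(d_fine), params$cutoff / 2) * (pi / 2)
  lo <- lo_fine[seq(1, nrow(lo_fine), 2), seq(1, ncol(lo_fine), 2)]
  hi <- u - lowpass_gaussian(u, params$cutoff)
  et <- estimate_eta(hi, lo, params$cutoff)
  out <- pmax(hi + params$alpha * et$eta * lo, 0)
  attr(out, "eta") <- et$eta
  attr(out, "eta_fallback") <- et$fallback
  out
}

#' Section all three pattern directions of a SPOT stack
#'
#' Runs [hilo_pair()] on the phase pair of every pattern direction for one
#' spectral channel, producing the three optically sectioned
#' polarization-modulated images.
#'
#' @param stack A `spot_stack`.
#' @param channel Channel label or index.
#' @param params A [hilo_params()]; defaults to the stack's pattern period
#'   and `alpha = 1`.
#' @return A `sectioned_stack`: three images plus channel and parameter echo.
#' @export
section_stack <- function(stack, channel = 1, params = NULL) {
  stopifnot(inherits(stack, "spot_stack"))
  cfg <- stack$config
  if (is.null(params)) {
    params <- hilo_params(pattern_period_px = cfg$pattern_period / cfg$pixel_size)
  }
  images <- lapply(1:3, function(k) {
    hilo_pair(stack$frames[[k]][[1]][[channel]],
              stack$frames[[k]][[2]][[channel]], params)
  })
  new_sectioned_stack(images,
                      channel = if (is.character(channel)) channel else cfg$channels[channel],
                      params = params, config = cfg)
}

#' @keywords internal
new_sectioned_stack <- function(images, channel, params, config = NULL) {
  stopifnot(length(images) == 3)
  structure(list(images = images, channel = channel, params = params,
                 config = config),
            class = "sectioned_stack")
}

#' @export
print.sectioned_stack <- function(x, ...) {
  sh <- dim(x$images[[1]])
  cat(sprintf("<sectioned_stack> 3 directions, %d x %d px, channel '%s', alpha = %g, cutoff = %.4g cyc/px\n",
              sh[1], sh[2], x$channel, x$params$alpha, x$params$cutoff))
  invisible(x)
}

#' SPOT intensity image
#'
#' Pixel-wise mean of the three optically sectioned direction images of one
#' channel.
#'
#' @param sectioned A `sectioned_stack` (or list of exactly three matrices).
#' @return Intensity image (matrix).
#' @export
spot_intensity <- function(sectioned) {
  imgs <- if (inherits(sectioned, "sectioned_stack")) sectioned$images else sectioned
  if (length(imgs) != 3) {
    stop("SPOT intensity requires exactly three sectioned images", call. = FALSE)
  }
  (imgs[[1]] + imgs[[2]] + imgs[[3]]) / 3
}

#' Adapt a five-phase SIM direction to a HiLo phase pair
#'
#' For one pattern direction of a five-phase SIM acquisition, the uniform
#' image is the mean of the five phases and the structured image is the first
#' phase. A complementary pi-shifted phase image is synthesized as
#' `2*uniform - structured` so the standard two-phase HiLo path can consume
#' SIM data unchanged.
#'
#' @param five_phase_images List of exactly five same-shaped matrices, one
#'   pattern direction, phases in acquisition order.
#' @return List with `i0` (structured), `ipi` (synthesized complement) and
#'   `uniform`.
#' @export
sim5_to_pair <- function(five_phase_images) {
  if (!is.list(five_phase_images) || length(five_phase_images) != 5) {
    stop("expected exactly five phase images", call. = FALSE)
  }
  dims <- lapply(five_phase_images, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("phase images must share one shape", call. = FALSE)
  }
  uniform <- Reduce(`+`, five_phase_images) / 5
  structured <- five_phase_images[[1]]
  list(i0 = structured, ipi = 2 * uniform - structured, uniform = uniform)
}
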