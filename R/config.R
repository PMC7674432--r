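#' Optical configuration for SPOT simulation and reconstruction
#'
#' Bundles the optical parameters shared by the forward simulator and the
#' reconstruction pipeline: PSF widths, pixel size, illumination pattern
#' geometry, excitation polarization convention, channel gains and noise
#' levels.
#'
#' The excitation polarization for pattern direction \eqn{\theta_k} is
#' \eqn{\theta_k + } `excitation_polarization_offset`. The default offset of
#' \eqn{\pi/2} encodes the s-polarization convention: the interfering beams
#' are polarized perpendicular to the plane of incidence, so the sample-plane
#' excitation field is perpendicular to the pattern wavevector.
#'
#' @param fwhm_lateral,fwhm_axial PSF full widths at half maximum (nm).
#' @param pixel_size Sample-plane pixel pitch (nm/px).
#' @param pattern_angles Three distinct pattern directions (radians), spanning
#'   `[0, pi)`.
#' @param pattern_period Illumination stripe period at the sample (nm).
#' @param pattern_phases Two phases differing by `pi` (radians).
#' @param excitation_polarization_offset Angle added to each pattern direction
#'   to obtain the excitation polarization (radians).
#' @param channels Character vector of spectral channel labels. The first two
#'   are the default emission-ratio pair (numerator, denominator).
#' @param channel_gains Named numeric gains per channel (linear, unitless).
#' @param channel_split Convention distributing an emitter's brightness `B`
#'   over the ratio pair given its emission ratio `rho`:
#'   `"equal_total"` sends `B*rho/(1+rho)` to the numerator and `B/(1+rho)` to
#'   the denominator (total preserved); `"equal_denominator"` sends `B*rho`
#'   to the numerator and `B` to the denominator. Either way the noiseless
#'   channel quotient equals `rho`.
#' @param background Expected background (photons/pixel/frame).
#' @param read_noise_sd Gaussian read noise, photons-equivalent.
#' @param image_shape Integer `c(ny, nx)` frame size in pixels.
#' @return An object of class `spot_config` (a validated list).
#' @examples
#' cfg <- spot_config(image_shape = c(64, 64))
#' excitation_angles(cfg) / pi
#' @export
spot_config <- function(fwhm_lateral = 230,
                        fwhm_axial = 670,
                        pixel_size = 65,
                        pattern_angles = c(0, pi / 3, 2 * pi / 3),
                        pattern_period = 230,
                        pattern_phases = c(0, pi),
                        excitation_polarization_offset = pi / 2,
                        channels = c("red", "green"),
                        channel_gains = NULL,
                        channel_split = c("equal_total", "equal_denominator"),
                        background = 0,
                        read_noise_sd = 1,
                        image_shape = c(128, 128)) {
  channel_split <- match.arg(channel_split)
  stopifnot(
    is.numeric(fwhm_lateral), fwhm_lateral > 0,
    is.numeric(fwhm_axial), fwhm_axial > 0,
    is.numeric(pixel_size), pixel_size > 0,
    is.numeric(pattern_period), pattern_period > 0,
    length(pattern_angles) == 3,
    length(pattern_phases) == 2,
    background >= 0, read_noise_sd >= 0,
    length(image_shape) == 2, all(image_shape >= 1)
  )
  ang <- pattern_angles %% pi
  if (min(dist(ang)) < 1e-9) {
    stop("`pattern_angles` must be three distinct directions modulo pi", call. = FALSE)
  }
  if (abs(abs(diff(pattern_phases)) - pi) > 1e-9) {
    stop("`pattern_phases` must differ by pi", call. = FALSE)
  }
  if (length(channels) < 1) stop("at least one channel required", call. = FALSE)
  if (is.null(channel_gains)) {
    channel_gains <- stats::setNames(rep(1, length(channels)), channels)
  }
  if (!all(channels %in% names(channel_gains))) {
    stop("`channel_gains` must name every channel", call. = FALSE)
  }
  structure(
    list(
      fwhm_lateral = fwhm_lateral,
      fwhm_axial = fwhm_axial,
      pixel_size = pixel_size,
      pattern_angles = pattern_angles,
      pattern_period = pattern_period,
      pattern_phases = pattern_phases,
      excitation_polarization_offset = excitation_polarization_offset,
      channels = channels,
      channel_gains = channel_gains[channels],
      channel_split = channel_split,
      background = background,
      read_noise_sd = read_noise_sd,
      image_shape = as.integer(image_shape)
    ),
    class = "spot_config"
  )
}

#' @export
print.spot_config <- function(x, ...) {
  cat("<spot_config>\n")
  cat(sprintf("  PSF FWHM: %g nm lateral / %g nm axial; pixel %g nm\n",
              x$fwhm_lateral, x$fwhm_axial, x$pixel_size))
  cat(sprintf("  pattern: period %g nm, directions %s deg, phases %s\n",
              x$pattern_period,
              paste(round(x$pattern_angles * 180 / pi, 1), collapse = "/"),
              paste(round(x$pattern_phases / pi, 2) * 180, collapse = "/")))
  cat(sprintf("  channels: %s (split: %s)\n",
              paste(x$channels, collapse = ", "), x$channel_split))
  cat(sprintf("  frame: %d x %d px, background %g, read noise %g\n",
              x$image_shape[1], x$image_shape[2], x$background, x$read_noise_sd))
  invisible(x)
}

#' Excitation polarization angles of a configuration
#'
#' Pattern directions plus the polarization offset, one angle per pattern
#' direction.
#'
#' @param config A [spot_config()].
#' @return Numeric vector of three angles (radians).
#' @export
excitation_angles <- function(config) {
  stopifnot(inherits(config, "spot_config"))
  config$pattern_angles + config$excitation_polarization_offset
}

#' @keywords internal
sigma_lateral_px <- function(config) {
  config$fwhm_lateral / (2 * sqrt(2 * log(2))) / config$pixel_size
}
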