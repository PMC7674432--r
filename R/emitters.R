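#' Dipole emitter table
#'
#' Builds and validates the ground-truth emitter table consumed by the
#' forward simulator. Each row is one point emitter: an in-plane fluorescent
#' dipole with a spectral emission ratio and a wobble-limited polarization
#' response.
#'
#' @param x,y,z Positions in nm, sample coordinates; `z = 0` is the focal
#'   plane; x increases to the right, y downward; pixel centers sit at
#'   integer multiples of the pixel size (0-based).
#' @param brightness Expected photons per uniformly illuminated frame.
#' @param emission_ratio Dimensionless quotient of the numerator over the
#'   denominator spectral channel of the emitter's emission (`> 0`).
#' @param orientation In-plane dipole axis angle from the +x axis (radians);
#'   normalized into `[0, pi)`.
#' @param wobble Polarization modulation depth of the emitter in `[0, 1]`:
#'   1 is an ideal fixed dipole, 0 a free rotor.
#' @return A tibble of class `dipole_emitters`.
#' @examples
#' dipole_emitters(x = c(0, 500), y = 100, z = c(0, 300),
#'                 emission_ratio = c(1, 0.5),
#'                 orientation = c(0, pi / 3))
#' @export
dipole_emitters <- function(x, y, z = 0, brightness = 1000,
                            emission_ratio = 1, orientation = 0,
                            wobble = 1) {
  out <- tibble::tibble(
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    brightness = as.numeric(brightness),
    emission_ratio = as.numeric(emission_ratio),
    orientation = as.numeric(orientation) %% pi,
    wobble = as.numeric(wobble)
  )
  validate_emitters(out)
}

#' @keywords internal
validate_emitters <- function(em) {
  if (nrow(em) == 0) stop("emitter table is empty", call. = FALSE)
  if (any(!is.finite(as.matrix(em[c("x", "y", "z")])))) {
    stop("emitter positions must be finite", call. = FALSE)
  }
  if (any(em$brightness < 0)) stop("`brightness` must be >= 0", call. = FALSE)
  if (any(em$emission_ratio <= 0)) stop("`emission_ratio` must be > 0", call. = FALSE)
  if (any(em$wobble < 0 | em$wobble > 1)) {
    stop("`wobble` modulation depth must lie in [0, 1]", call. = FALSE)
  }
  class(em) <- unique(c("dipole_emitters", class(em)))
  em
}

#' Polarized excitation response of a wobbling dipole
#'
#' Relative excitation efficiency of an in-plane dipole of orientation `phi`
#' and wobble modulation depth `m` under linearly polarized excitation at
#' angle `theta_exc`:
#' \deqn{r = 1 + m \cos(2(\theta_{exc} - \phi)).}
#' The mean over excitation angle is 1, so polarization modulation does not
#' change the total collected signal over a full modulation cycle.
#'
#' @param theta_exc Excitation polarization angle (radians).
#' @param phi Dipole orientation (radians).
#' @param m Modulation depth in `[0, 1]`.
#' @return Response weight in `[0, 2]`; vectorized over all arguments.
#' @examples
#' excitation_response(0, 0, 1)        # aligned ideal dipole: 2
#' excitation_response(1.2, 0.3, 0)    # free rotor: 1
#' @export
excitation_response <- function(theta_exc, phi, m) {
  if (any(m < 0 | m > 1)) stop("`m` must lie in [0, 1]", call. = FALSE)
  1 + m * cos(2 * (theta_exc - phi))
}

#' Detection weight of a displaced emitter
#'
#' Separable Gaussian point-spread weight: the relative contribution of an
#' emitter displaced by `(dx, dy, dz)` from a pixel's line of sight,
#' \deqn{w = \exp(-4\ln 2\,(dx^2+dy^2)/\mathrm{FWHM}_{lat}^2)\,
#'           \exp(-4\ln 2\, dz^2/\mathrm{FWHM}_{ax}^2),}
#' normalized to 1 at the origin. The axial factor describes the falloff of a
#' point emitter's peak; see the methods vignette for how extended defocused
#' layers are treated.
#'
#' @param dx,dy,dz Displacements in nm.
#' @param config A [spot_config()] supplying the FWHMs.
#' @return Weight in `(0, 1]`; vectorized.
#' @examples
#' cfg <- spot_config()
#' psf_weight(0, 0, 0, cfg)     # 1
#' psf_weight(230, 0, 0, cfg)   # 2^-4
#' @export
psf_weight <- function(dx, dy, dz, config) {
  stopifnot(inherits(config, "spot_config"))
  l2 <- 4 * log(2)
  exp(-l2 * (dx^2 + dy^2) / config$fwhm_lateral^2) *
    exp(-l2 * dz^2 / config$fwhm_axial^2)
}

#' @keywords internal
#' Fraction of an emitter's brightness landing in each ratio channel.
#' Returns a named vector over config$channels. Channels beyond the ratio
#' pair receive 0 (the simulator models the two-channel ratiometric path).
channel_split_weights <- function(rho, config) {
  chans <- config$channels
  w <- stats::setNames(rep(0, length(chans)), chans)
  if (length(chans) == 1) {
    w[1] <- 1
    return(w)
  }
  num <- chans[1]
  den <- chans[2]
  if (config$channel_split == "equal_total") {
    w[num] <- rho / (1 + rho)
    w[den] <- 1 / (1 + rho)
  } else { # equal_denominator
    w[num] <- rho
    w[den] <- 1
  }
  w
}
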