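#' Polarization harmonic analysis of three modulated images
#'
#' Computes the 0th and ±1st harmonics of the pixel intensity along the
#' polarization dimension. With excitation polarization angles
#' \eqn{\theta_k} and direction images \eqn{I_k},
#' \deqn{a_0 = \tfrac13\sum_k I_k, \qquad
#'       a_1 = \tfrac23\sum_k I_k e^{-2i\theta_k},}
#' the modulation depth is \eqn{m = |a_1|/a_0} (clipped to `[0, 1]`) and the
#' dipole orientation \eqn{\phi = (-\arg a_1)/2 \bmod \pi}. For a pure
#' cosine response \eqn{I_k = A(1 + m_0\cos 2(\theta_k - \phi_0))} at three
#' equally spaced angles the estimator is exact: \eqn{m = m_0},
#' \eqn{\phi = \phi_0}. Unequally spaced angle sets are rejected, which is
#' what keeps that exactness contract.
#'
#' @param sectioned A `sectioned_stack` (angles taken from its
#'   configuration's excitation polarizations) or a list of three matrices.
#' @param theta_exc Three excitation polarization angles (radians); required
#'   when `sectioned` is a bare list.
#' @return A `polarization_maps` object: `a0`, complex `a1`, `m`
#'   (clipped), `m_raw`, `phi`, and a validity `mask` (initially
#'   `a0 > 0`).
#' @examples
#' th <- c(0, pi / 3, 2 * pi / 3)
#' imgs <- lapply(th, function(t) matrix(1 + 0.6 * cos(2 * (t - pi / 6)), 2, 2))
#' maps <- polarization_harmonics(imgs, th)
#' c(maps$m[1], maps$phi[1] * 180 / pi)
#' @export
polarization_harmonics <- function(sectioned, theta_exc = NULL) {
  if (inherits(sectioned, "sectioned_stack")) {
    imgs <- sectioned$images
    if (is.null(theta_exc)) {
      if (is.null(sectioned$config)) {
        stop("no configuration attached; supply `theta_exc`", call. = FALSE)
      }
      theta_exc <- excitation_angles(sectioned$config)
    }
  } else {
    imgs <- sectioned
  }
  if (length(imgs) != 3) stop("exactly three direction images required", call. = FALSE)
  if (is.null(theta_exc) || length(theta_exc) != 3) {
    stop("exactly three excitation angles required", call. = FALSE)
  }
  ang <- sort(theta_exc %% pi)
  gaps <- diff(c(ang, ang[1] + pi))
  if (min(gaps) < 1e-9) {
    stop("excitation angles must be distinct modulo pi", call. = FALSE)
  }
  if (max(abs(gaps - pi / 3)) > 1e-6) {
    stop("excitation angles must be equally spaced (pi/3 apart) modulo pi",
         call. = FALSE)
  }
  dims <- lapply(imgs, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("direction images must share one shape", call. = FALSE)
  }
  a0 <- (imgs[[1]] + imgs[[2]] + imgs[[3]]) / 3
  a1 <- (2 / 3) * (imgs[[1]] * exp(-2i * theta_exc[1]) +
                     imgs[[2]] * exp(-2i * theta_exc[2]) +
                     imgs[[3]] * exp(-2i * theta_exc[3]))
  m_raw <- matrix(NA_real_, nrow(a0), ncol(a0))
  pos <- a0 > 0
  m_raw[pos] <- Mod(a1[pos]) / a0[pos]
  phi <- (-Arg(a1) / 2) %% pi
  phi[!pos] <- NA_real_
  phi[!is.na(m_raw) & m_raw < 1e-12] <- NA_real_ # no modulation: undefined
  structure(
    list(a0 = a0, a1 = a1, m = pmin(m_raw, 1), m_raw = m_raw, phi = phi,
         mask = pos, theta_exc = theta_exc),
    class = "polarization_maps"
  )
}

#' @export
print.polarization_maps <- function(x, ...) {
  cat(sprintf("<polarization_maps> %d x %d px; %d/%d pixels valid\n",
              nrow(x$a0), ncol(x$a0), sum(x$mask), length(x$mask)))
  cat(sprintf("  excitation angles: %s deg\n",
              paste(round(x$theta_exc * 180 / pi, 1), collapse = "/")))
  if (any(x$mask)) {
    cat(sprintf("  modulation depth: median %.3f; a0 max %.4g\n",
                stats::median(x$m[x$mask]), max(x$a0)))
  }
  invisible(x)
}

#' Restrict polarization maps to reliable pixels
#'
#' Masks pixels whose mean intensity is at or below `intensity_threshold` and
#' pixels whose raw (unclipped) modulation depth exceeds `1 + m_tolerance` —
#' unphysical values produced by noise rather than modulation.
#'
#' @param maps A [polarization_harmonics()] result.
#' @param intensity_threshold Minimum `a0` (exclusive) for a valid pixel.
#' @param m_tolerance Allowed overshoot of the raw modulation depth above 1.
#' @return The maps with an updated `mask`; `m` stays clipped to `[0, 1]`
#'   on kept pixels.
#' @export
validity_mask <- function(maps, intensity_threshold = 0, m_tolerance = 0.1) {
  stopifnot(inherits(maps, "polarization_maps"),
            intensity_threshold >= 0, m_tolerance >= 0)
  keep <- maps$a0 > intensity_threshold &
    !is.na(maps$m_raw) & maps$m_raw <= 1 + m_tolerance
  maps$mask <- keep
  maps
}

#' Pixel table of polarization maps
#'
#' @param x A `polarization_maps` object.
#' @param ... Unused.
#' @return A tibble with one row per pixel: `x`, `y` (0-based), `a0`, `m`,
#'   `phi` and `mask`.
#' @export
tidy.polarization_maps <- function(x, ...) {
  ny <- nrow(x$a0)
  nx <- ncol(x$a0)
  out <- tibble::tibble(
    x = rep(0:(nx - 1), each = ny),
    y = rep(0:(ny - 1), times = nx)
  )
  out$a0 <- as.vector(x$a0)
  out$m <- as.vector(x$m)
  out$phi <- as.vector(x$phi)
  out$mask <- as.vector(x$mask)
  out
}

#' @export
glance.polarization_maps <- function(x, ...) {
  ok <- x$mask & !is.na(x$m)
  tibble::tibble(
    n_valid = sum(ok),
    mean_m = if (any(ok)) mean(x$m[ok]) else NA_real_,
    median_m = if (any(ok)) stats::median(x$m[ok]) else NA_real_,
    mean_a0 = mean(x$a0)
  )
}
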