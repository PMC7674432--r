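#' Emission-ratio (lipid polarity) map
#'
#' Pixel-wise quotient of two registered, sectioned and flat-field-corrected
#' spectral channel images. For a solvatochromic membrane dye the
#' longer-wavelength / shorter-wavelength ratio rises with lipid polarity
#' (the emission red-shifts in polar lipids), so the map is a polarity proxy.
#'
#' @param numerator,denominator Same-shape channel intensity images; by
#'   convention numerator is the longer-wavelength channel.
#' @param threshold Minimum denominator intensity (exclusive) for a valid
#'   pixel; pixels at or below it are masked, never divided. A practical
#'   default is three times the read-noise standard deviation.
#' @param channels Optional channel-pair labels `c(numerator, denominator)`.
#' @return A `polarity_map`: `ratio` (NA off-mask), `mask`, `channels`.
#' @examples
#' den <- matrix(10, 4, 4)
#' emission_ratio_map(den * 0.5, den, threshold = 1)$ratio[1, 1]
#' @export
emission_ratio_map <- function(numerator, denominator, threshold = 0,
                               channels = c("red", "green")) {
  stopifnot(is.matrix(numerator), is.matrix(denominator))
  if (!all(dim(numerator) == dim(denominator))) {
    stop("channel images must have the same shape", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold < 0) {
    stop("`threshold` must be >= 0", call. = FALSE)
  }
  mask <- is.finite(denominator) & denominator > threshold
  ratio <- matrix(NA_real_, nrow(numerator), ncol(numerator))
  ratio[mask] <- numerator[mask] / denominator[mask]
  structure(list(ratio = ratio, mask = mask, channels = channels),
            class = "polarity_map")
}

#' @export
print.polarity_map <- function(x, ...) {
  cat(sprintf("<polarity_map> %s / %s, %d x %d px; %d/%d pixels valid\n",
              x$channels[1], x$channels[2], nrow(x$ratio), ncol(x$ratio),
              sum(x$mask), length(x$mask)))
  if (any(x$mask)) {
    cat(sprintf("  ratio: median %.3f [%.3f, %.3f]\n",
                stats::median(x$ratio[x$mask]),
                min(x$ratio[x$mask]), max(x$ratio[x$mask])))
  }
  invisible(x)
}

#' @export
tidy.polarity_map <- function(x, ...) {
  ny <- nrow(x$ratio)
  nx <- ncol(x$ratio)
  out <- tibble::tibble(
    x = rep(0:(nx - 1), each = ny),
    y = rep(0:(ny - 1), times = nx)
  )
  out$ratio <- as.vector(x$ratio)
  out$mask <- as.vector(x$mask)
  out
}
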