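#' 2D affine transform between detection channels
#'
#' @param linear 2x2 linear part (rotation/scale/shear), pixel units.
#' @param translation Length-2 translation `(tx, ty)` in pixels.
#' @return A `spot_affine` object wrapping the 2x3 matrix
#'   `[linear | translation]` acting on 0-based pixel-center coordinates
#'   `(x, y)`.
#' @examples
#' affine_transform(translation = c(5, -3))
#' @export
affine_transform <- function(linear = diag(2), translation = c(0, 0)) {
  stopifnot(all(dim(linear) == c(2, 2)), length(translation) == 2)
  new_affine(cbind(linear, translation))
}

#' @keywords internal
new_affine <- function(m, rms = NA_real_, n_pairs = NA_integer_,
                       n_dropped = NA_integer_) {
  m <- matrix(as.numeric(m), 2, 3)
  if (abs(det(m[, 1:2])) < 1e-6) {
    stop("affine linear part is singular", call. = FALSE)
  }
  structure(list(matrix = m, rms = rms, n_pairs = n_pairs,
                 n_dropped = n_dropped),
            class = "spot_affine")
}

#' @keywords internal
as_affine <- function(x) {
  if (inherits(x, "spot_affine")) return(x)
  if (is.matrix(x) && all(dim(x) == c(2, 3))) return(new_affine(x))
  stop("expected a `spot_affine` or a 2x3 matrix", call. = FALSE)
}

#' @export
print.spot_affine <- function(x, ...) {
  cat("<spot_affine> [linear | translation], px:\n")
  print(round(x$matrix, 6))
  if (!is.na(x$rms)) {
    cat(sprintf("  fitted on %d pairs (%d unmatched dropped), RMS residual %.4g px\n",
                x$n_pairs, x$n_dropped, x$rms))
  }
  invisible(x)
}

#' @keywords internal
apply_affine_points <- function(tf, x, y) {
  m <- as_affine(tf)$matrix
  list(x = m[1, 1] * x + m[1, 2] * y + m[1, 3],
       y = m[2, 1] * x + m[2, 2] * y + m[2, 3])
}

#' @keywords internal
invert_affine <- function(tf) {
  m <- as_affine(tf)$matrix
  ainv <- solve(m[, 1:2])
  new_affine(cbind(ainv, -ainv %*% m[, 3]))
}

#' Localize isolated emitters by thresholded weighted centroids
#'
#' Segments pixels above `intensity_threshold` into connected components and
#' returns one sub-pixel localization per component: the intensity-weighted
#' centroid over the component plus a one-pixel dilation ring. Adequate for
#' isolated fiducial beads; no Gaussian fitting is attempted.
#'
#' @param image 2D numeric matrix.
#' @param intensity_threshold Absolute threshold; must exceed the background.
#' @return An `emitter_localizations` tibble with columns `x`, `y` (0-based
#'   pixel-center coordinates), `peak` and `n_px`. Empty when nothing exceeds
#'   the threshold.
#' @export
localize_emitters <- function(image, intensity_threshold) {
  stopifnot(is.matrix(image), is.numeric(intensity_threshold),
            intensity_threshold >= 0)
  mask <- image > intensity_threshold
  empty <- tibble::tibble(x = numeric(), y = numeric(),
                          peak = numeric(), n_px = integer())
  class(empty) <- unique(c("emitter_localizations", class(empty)))
  if (!any(mask)) return(empty)
  labels <- EBImage::bwlabel(mask)
  nlab <- max(labels)
  ny <- nrow(image)
  nx <- ncol(image)
  res <- vector("list", nlab)
  idx_all <- which(labels > 0, arr.ind = TRUE)
  lab_of <- labels[labels > 0]
  for (l in seq_len(nlab)) {
    comp <- idx_all[lab_of == l, , drop = FALSE]
    # component plus 1-px (8-connected) dilation ring
    rows <- pmin(pmax(rep(comp[, 1], each = 9) + rep(-1:1, times = 3), 1), ny)
    cols <- pmin(pmax(rep(comp[, 2], each = 9) +
                        rep(rep(-1:1, each = 3), times = 1), 1), nx)
    cells <- unique(cbind(rows, cols))
    w <- image[cells]
    w <- pmax(w, 0)
    sw <- sum(w)
    res[[l]] <- c(
      x = sum(w * (cells[, 2] - 1)) / sw,
      y = sum(w * (cells[, 1] - 1)) / sw,
      peak = max(image[comp]),
      n_px = nrow(comp)
    )
  }
  out <- tibble::as_tibble(do.call(rbind, res))
  out$n_px <- as.integer(out$n_px)
  class(out) <- unique(c("emitter_localizations", class(out)))
  out
}

#' Fit a 2D affine registration between two localization sets
#'
#' Matches localizations by mutual nearest neighbour within `radius`, then
#' least-squares fits the affine transform minimizing
#' \eqn{\sum \|T(src) - dst\|^2}.
#'
#' @param src,dst `emitter_localizations` tibbles (or anything with `x`, `y`
#'   columns). When the two sets are already in one-to-one row
#'   correspondence, set `matched = TRUE` to skip matching.
#' @param radius Mutual nearest-neighbour match radius (px).
#' @param matched If `TRUE`, rows are taken as corresponding pairs.
#' @return A fitted `spot_affine` carrying the RMS residual, the number of
#'   pairs used and the number of unmatched localizations dropped.
#' @export
fit_affine <- function(src, dst, radius = 5, matched = FALSE) {
  sx <- cbind(src$x, src$y)
  dx <- cbind(dst$x, dst$y)
  if (matched) {
    if (nrow(sx) != nrow(dx)) stop("matched sets must have equal size", call. = FALSE)
    pairs <- cbind(seq_len(nrow(sx)), seq_len(nrow(dx)))
  } else {
    d2 <- outer(sx[, 1], dx[, 1], "-")^2 + outer(sx[, 2], dx[, 2], "-")^2
    nn_sd <- apply(d2, 1, which.min)
    nn_ds <- apply(d2, 2, which.min)
    keep <- which(nn_ds[nn_sd] == seq_len(nrow(sx)) &
                    d2[cbind(seq_len(nrow(sx)), nn_sd)] <= radius^2)
    pairs <- cbind(keep, nn_sd[keep])
  }
  n_dropped <- (nrow(sx) - nrow(pairs)) + (nrow(dx) - nrow(pairs))
  if (n_dropped > 0) {
    message(sprintf("fit_affine: dropped %d unmatched localization(s)", n_dropped))
  }
  if (nrow(pairs) < 3) {
    stop("need at least 3 matched pairs to fit an affine transform", call. = FALSE)
  }
  s <- sx[pairs[, 1], , drop = FALSE]
  d <- dx[pairs[, 2], , drop = FALSE]
  sc <- sweep(s, 2, colMeans(s))
  if (min(svd(sc)$d) < 1e-8 * max(svd(sc)$d)) {
    stop("degenerate geometry: matched points are collinear", call. = FALSE)
  }
  X <- cbind(s, 1)
  beta <- solve(crossprod(X), crossprod(X, d)) # 3 x 2
  m <- t(beta)                                  # 2 x 3 [linear | translation]
  fit <- X %*% beta
  rms <- sqrt(mean(rowSums((fit - d)^2)))
  new_affine(m, rms = rms, n_pairs = nrow(pairs), n_dropped = as.integer(n_dropped))
}

#' @importFrom generics tidy
#' @export
tidy.spot_affine <- function(x, ...) {
  m <- x$matrix
  tibble::tibble(
    term = c("a11", "a12", "a21", "a22", "tx", "ty"),
    estimate = c(m[1, 1], m[1, 2], m[2, 1], m[2, 2], m[1, 3], m[2, 3])
  )
}

#' @importFrom generics glance
#' @export
glance.spot_affine <- function(x, ...) {
  tibble::tibble(rms = x$rms, n_pairs = x$n_pairs, n_dropped = x$n_dropped,
                 det = det(x$matrix[, 1:2]))
}

#' Resample an image under an affine transform
#'
#' Warps `image` so that a feature located at `p` in the input appears at
#' `T(p)` in the output: each output pixel `q` is bilinearly interpolated at
#' `T^{-1}(q)`. Out-of-bounds samples are zero; the shape is preserved.
#'
#' @param image 2D numeric matrix.
#' @param transform A `spot_affine` (or 2x3 matrix).
#' @return Matrix of the same shape.
#' @export
apply_transform <- function(image, transform) {
  stopifnot(is.matrix(image))
  tf <- as_affine(transform)
  inv <- invert_affine(tf)$matrix
  ny <- nrow(image)
  nx <- ncol(image)
  qx <- rep(0:(nx - 1), each = ny)
  qy <- rep(0:(ny - 1), times = nx)
  sx <- inv[1, 1] * qx + inv[1, 2] * qy + inv[1, 3]
  sy <- inv[2, 1] * qx + inv[2, 2] * qy + inv[2, 3]
  x0 <- floor(sx)
  y0 <- floor(sy)
  fx <- sx - x0
  fy <- sy - y0
  val <- function(xi, yi) {
    ok <- xi >= 0 & xi <= nx - 1 & yi >= 0 & yi <= ny - 1
    v <- numeric(length(xi))
    v[ok] <- image[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  out <- (1 - fx) * (1 - fy) * val(x0, y0) +
    fx * (1 - fy) * val(x0 + 1, y0) +
    (1 - fx) * fy * val(x0, y0 + 1) +
    fx * fy * val(x0 + 1, y0 + 1)
  matrix(out, ny, nx)
}

#' @keywords internal
#' Separable Gaussian smoothing with edge renormalization: smoothing a
#' constant image returns it exactly, and borders carry no roll-off bias.
smooth_gaussian_norm <- function(img, sigma) {
  band <- function(n) {
    d <- outer(seq_len(n), seq_len(n), "-")
    k <- exp(-d^2 / (2 * sigma^2))
    k[abs(d) > 4 * sigma] <- 0
    k
  }
  kr <- band(nrow(img))
  kc <- band(ncol(img))
  num <- kr %*% img %*% kc
  den <- kr %*% matrix(1, nrow(img), ncol(img)) %*% kc
  num / den
}

#' Estimate an illumination flat-field map from calibration images
#'
#' Averages the supplied bead-slide calibration images, extracts the smooth
#' illumination envelope with a large Gaussian kernel (default
#' `sigma = width/8` px), and normalizes the result to unit mean.
#'
#' @param calibration_images A matrix or list of same-shaped matrices.
#' @param sigma Smoothing scale (px); default `ncol(image)/8`.
#' @return A `flatfield_map`: a strictly positive, unit-mean matrix.
#' @export
estimate_flatfield <- function(calibration_images, sigma = NULL) {
  if (is.matrix(calibration_images)) calibration_images <- list(calibration_images)
  stopifnot(length(calibration_images) >= 1)
  avg <- Reduce(`+`, calibration_images) / length(calibration_images)
  if (mean(avg) <= 0) stop("calibration images have no signal", call. = FALSE)
  if (is.null(sigma)) sigma <- ncol(avg) / 8
  sm <- smooth_gaussian_norm(avg, sigma)
  if (any(sm <= 0)) {
    stop("flat-field envelope is not strictly positive; calibration too sparse",
         call. = FALSE)
  }
  out <- sm / mean(sm)
  class(out) <- c("flatfield_map", class(out))
  out
}

#' Compensate illumination nonuniformity in a raw stack
#'
#' Divides all six frames (every direction, phase and channel) pixel-wise by
#' the unit-mean flat-field map.
#'
#' @param stack A `spot_stack`.
#' @param map A [estimate_flatfield()] result (unit-mean positive matrix).
#' @return The corrected `spot_stack`.
#' @export
correct_flatfield <- function(stack, map) {
  stopifnot(inherits(stack, "spot_stack"))
  map <- unclass(map)
  stopifnot(is.matrix(map))
  if (any(map <= 0)) stop("flat-field map must be strictly positive", call. = FALSE)
  if (abs(mean(map) - 1) > 1e-6) {
    stop("flat-field map must have unit mean (use estimate_flatfield())",
         call. = FALSE)
  }
  if (!all(dim(map) == dim(stack$frames[[1]][[1]][[1]]))) {
    stop("flat-field shape does not match the stack", call. = FALSE)
  }
  map_frames(stack, function(fr) fr / map)
}
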