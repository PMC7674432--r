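#' Sample a map along a polyline band
#'
#' Walks the polyline in 1-px arc-length steps and, at every step, samples
#' the map by nearest-pixel lookup across a perpendicular band of
#' `2*halfwidth + 1` pixels. Masked, out-of-bounds and NA pixels are
#' excluded. This mirrors measuring organelle profiles drawn on the
#' intensity image and read off the emission-ratio or modulation-depth maps.
#'
#' @param map 2D numeric matrix.
#' @param polyline Data frame with `x`, `y` vertex columns (px, 0-based
#'   pixel-center coordinates), at least two vertices.
#' @param halfwidth Half-width of the sampling band (px, integer >= 0).
#' @param mask Optional logical matrix; `FALSE` pixels are excluded.
#' @return A `polyline_measurement`: sampled `values`, their `mean`, `sd`
#'   and `n`, plus the vertices and half-width used.
#' @export
sample_polyline <- function(map, polyline, halfwidth = 0, mask = NULL) {
  stopifnot(is.matrix(map), halfwidth >= 0)
  vx <- as.numeric(polyline$x)
  vy <- as.numeric(polyline$y)
  if (length(vx) < 2) stop("a polyline needs at least two vertices", call. = FALSE)
  ny <- nrow(map)
  nx <- ncol(map)
  seg_len <- sqrt(diff(vx)^2 + diff(vy)^2)
  total <- sum(seg_len)
  if (total == 0) stop("polyline has zero length", call. = FALSE)
  s_vert <- c(0, cumsum(seg_len))
  s <- seq(0, total, by = 1)
  seg <- findInterval(s, s_vert, rightmost.closed = TRUE)
  seg <- pmin(seg, length(seg_len))
  t_loc <- (s - s_vert[seg]) / seg_len[seg]
  cx <- vx[seg] + t_loc * diff(vx)[seg]
  cy <- vy[seg] + t_loc * diff(vy)[seg]
  tx <- diff(vx)[seg] / seg_len[seg]
  ty <- diff(vy)[seg] / seg_len[seg]
  offs <- -halfwidth:halfwidth
  px <- round(rep(cx, each = length(offs)) + offs * rep(-ty, each = length(offs)))
  py <- round(rep(cy, each = length(offs)) + offs * rep(tx, each = length(offs)))
  ok <- px >= 0 & px <= nx - 1 & py >= 0 & py <= ny - 1
  if (!is.null(mask)) {
    ok[ok] <- mask[cbind(py[ok] + 1, px[ok] + 1)]
  }
  vals <- map[cbind(py[ok] + 1, px[ok] + 1)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stop("nothing measurable: every sample is masked or out of bounds",
         call. = FALSE)
  }
  structure(
    list(values = vals, mean = mean(vals),
         sd = if (length(vals) > 1) stats::sd(vals) else 0,
         n = length(vals),
         vertices = tibble::tibble(x = vx, y = vy), halfwidth = halfwidth),
    class = "polyline_measurement"
  )
}

#' @export
print.polyline_measurement <- function(x, ...) {
  cat(sprintf("<polyline_measurement> %d samples (halfwidth %d px): mean %.4g +/- %.4g\n",
              x$n, x$halfwidth, x$mean, x$sd))
  invisible(x)
}

#' @export
glance.polyline_measurement <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd, n = x$n, halfwidth = x$halfwidth)
}

#' Accept or reject repeated measurements by their fluctuation
#'
#' Repeated acquisitions of the same structure are accepted only when the
#' relative fluctuation `(max - min) / mean` is within the limit
#' (inclusive), the guard used against motion drift between repeats.
#'
#' @param values At least two repeated measurement values (finite, nonzero
#'   mean).
#' @param limit Acceptance limit on the fluctuation (default 0.15).
#' @return One-row tibble: `accepted`, `fluctuation`, `n`.
#' @examples
#' repeat_acceptance(c(1.0, 1.0, 1.2)) # fluctuation 0.1875: rejected
#' @export
repeat_acceptance <- function(values, limit = 0.15) {
  if (length(values) < 2) {
    stop("at least two repeated measurements are required", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  mu <- mean(values)
  if (mu == 0) stop("mean of the measurements is zero", call. = FALSE)
  fluct <- (max(values) - min(values)) / mu
  tibble::tibble(accepted = fluct <= limit, fluctuation = fluct,
                 n = length(values))
}

#' Fit a polarity-phase group ellipse
#'
#' Summarizes a group of (emission ratio, modulation depth) measurements by
#' its centroid and sample covariance. The sigma contour is the Mahalanobis
#' distance-1 ellipse of that covariance, and the 2-sigma contour distance 2.
#'
#' @param points Data frame whose first two numeric columns (or columns
#'   `ratio`, `depth`) hold the measurements; at least three non-collinear
#'   points.
#' @param label Group label.
#' @return A `group_ellipse`: `label`, `mean` (length 2), `cov` (2x2).
#' @export
fit_group_ellipse <- function(points, label = NULL) {
  if (all(c("ratio", "depth") %in% names(points))) {
    m <- cbind(points$ratio, points$depth)
  } else {
    num <- points[vapply(points, is.numeric, logical(1))]
    if (ncol(num) < 2) stop("need two numeric columns", call. = FALSE)
    m <- as.matrix(num[, 1:2])
  }
  if (nrow(m) < 3) stop("at least three points are required", call. = FALSE)
  cv <- stats::cov(m)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev), 1)) {
    stop("degenerate covariance: points are (near-)collinear", call. = FALSE)
  }
  structure(list(label = label %||% "group", mean = colMeans(m), cov = cv,
                 n = nrow(m)),
            class = "group_ellipse")
}

#' @export
print.group_ellipse <- function(x, ...) {
  cat(sprintf("<group_ellipse> '%s': centre (%.3f, %.3f), n = %d\n",
              x$label, x$mean[1], x$mean[2], x$n))
  invisible(x)
}

#' @export
tidy.group_ellipse <- function(x, ...) {
  tibble::tibble(
    label = x$label, mean_ratio = x$mean[1], mean_depth = x$mean[2],
    sd_ratio = sqrt(x$cov[1, 1]), sd_depth = sqrt(x$cov[2, 2]),
    cor = stats::cov2cor(x$cov)[1, 2], n = x$n
  )
}

#' Contour of a group ellipse
#'
#' Points on the Mahalanobis distance-`radius` contour, for plotting.
#'
#' @param ellipse A [fit_group_ellipse()] result.
#' @param radius Mahalanobis radius (1 = sigma contour, 2 = 2-sigma).
#' @param n Number of contour points.
#' @return Tibble with `ratio`, `depth` columns.
#' @export
ellipse_contour <- function(ellipse, radius = 1, n = 120) {
  stopifnot(inherits(ellipse, "group_ellipse"), radius > 0)
  th <- seq(0, 2 * pi, length.out = n)
  circ <- rbind(cos(th), sin(th)) * radius
  l <- chol(ellipse$cov)
  pts <- t(t(l) %*% circ) + rep(ellipse$mean, each = n)
  tibble::tibble(ratio = pts[, 1], depth = pts[, 2])
}

#' @keywords internal
mahalanobis2 <- function(point, ellipse) {
  d <- as.numeric(point) - ellipse$mean
  as.numeric(t(d) %*% solve(ellipse$cov, d))
}

#' Classify a compartment by exclusive ellipse membership
#'
#' A (ratio, depth) measurement is assigned a group label only when it falls
#' inside exactly one group's sigma contour; inside two or more it is
#' `"ambiguous"` (overlapping lipid properties, e.g. Golgi vs late
#' endosome), inside none `"unassigned"`.
#'
#' @param point Length-2 numeric `(ratio, depth)` or one-row data frame.
#' @param ellipses List of [fit_group_ellipse()] results.
#' @param radius Membership contour radius (Mahalanobis; default 1 = sigma).
#' @return A single character label.
#' @export
classify_compartment <- function(point, ellipses, radius = 1) {
  if (is.data.frame(point)) {
    point <- c(point$ratio[1], point$depth[1])
  }
  stopifnot(length(point) == 2, length(ellipses) >= 1)
  inside <- vapply(ellipses, function(e) mahalanobis2(point, e) <= radius^2,
                   logical(1))
  if (sum(inside) == 1) {
    ellipses[[which(inside)]]$label
  } else if (sum(inside) > 1) {
    "ambiguous"
  } else {
    "unassigned"
  }
}
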