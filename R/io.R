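#' Write a SPOT stack as a multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered direction-major, then phase, then channel — `(k, p, c)`
#' lexicographic. Pixel values are stored as 32-bit float normalized by a
#' single scale factor recorded in the sidecar, which also echoes the
#' configuration and any provenance (seed, emitter table).
#'
#' @param stack A `spot_stack`.
#' @param tif Output TIFF path.
#' @param json Sidecar path; defaults to the TIFF path with `.json`.
#' @return Invisibly, the sidecar list.
#' @export
write_spot_stack <- function(stack, tif,
                             json = paste0(tools::file_path_sans_ext(tif), ".json")) {
  stopifnot(inherits(stack, "spot_stack"))
  pages <- list()
  for (k in 1:3) {
    for (p in seq_along(stack$frames[[k]])) {
      for (ch in stack$config$channels) {
        pages <- c(pages, list(stack$frames[[k]][[p]][[ch]]))
      }
    }
  }
  scale <- max(1, vapply(pages, max, numeric(1)))
  lo <- min(0, vapply(pages, min, numeric(1)))
  scale <- scale - lo
  suppressWarnings(tiff::writeTIFF(lapply(pages, function(m) (m - lo) / scale),
                                   tif, bits.per.sample = 32L,
                                   compression = "none"))
  meta <- list(
    format = "spot_stack",
    page_order = "direction-major (k, p, c)",
    n_directions = 3L,
    n_phases = length(stack$frames[[1]]),
    channels = stack$config$channels,
    scale = scale, offset = lo,
    seed = stack$meta$seed,
    config = config_to_list(stack$config),
    emitters = if (!is.null(stack$meta$emitters)) {
      as.data.frame(stack$meta$emitters)
    }
  )
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(meta)
}

#' Read a SPOT stack written by [write_spot_stack()]
#'
#' @param tif TIFF path.
#' @param json Sidecar path.
#' @return A `spot_stack`.
#' @export
read_spot_stack <- function(tif,
                            json = paste0(tools::file_path_sans_ext(tif), ".json")) {
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  if (!identical(meta$format, "spot_stack")) {
    stop("sidecar does not describe a spot_stack", call. = FALSE)
  }
  config <- config_from_list(meta$config)
  pages <- tiff::readTIFF(tif, all = TRUE)
  pages <- lapply(pages, function(m) m * meta$scale + meta$offset)
  nc <- length(config$channels)
  np <- meta$n_phases
  expect <- 3L * np * nc
  if (length(pages) != expect) {
    i <- length(pages)
    k <- i %/% (np * nc) + 1L
    p <- (i %% (np * nc)) %/% nc + 1L
    stop(sprintf(
      "stack is incomplete: %d of %d pages; first missing frame is direction %d, phase %d",
      length(pages), expect, k, p), call. = FALSE)
  }
  frames <- empty_frames(config)
  i <- 0L
  for (k in 1:3) {
    for (p in seq_len(np)) {
      for (c in seq_len(nc)) {
        i <- i + 1L
        frames[[k]][[p]][[c]] <- pages[[i]]
      }
    }
  }
  meta_out <- list(seed = meta$seed)
  if (!is.null(meta$emitters)) {
    meta_out$emitters <- tibble::as_tibble(meta$emitters)
  }
  new_spot_stack(frames, config, meta = meta_out)
}

#' @keywords internal
config_to_list <- function(config) {
  lst <- unclass(config)
  lst$channel_gains <- as.list(lst$channel_gains) # keep names in JSON
  lst
}

#' @keywords internal
config_from_list <- function(lst) {
  spot_config(
    fwhm_lateral = lst$fwhm_lateral, fwhm_axial = lst$fwhm_axial,
    pixel_size = lst$pixel_size,
    pattern_angles = unlist(lst$pattern_angles),
    pattern_period = lst$pattern_period,
    pattern_phases = unlist(lst$pattern_phases),
    excitation_polarization_offset = lst$excitation_polarization_offset,
    channels = unlist(lst$channels),
    channel_gains = unlist(lst$channel_gains),
    channel_split = lst$channel_split,
    background = lst$background,
    read_noise_sd = lst$read_noise_sd,
    image_shape = unlist(lst$image_shape)
  )
}

#' Build a SPOT stack from bare frame matrices
#'
#' Validates that every (direction, phase) slot is present and names the
#' first missing one otherwise.
#'
#' @param frames Nested list `frames[[direction]][[phase]][[channel]]` of
#'   same-shaped nonnegative matrices (3 directions x 2 phases).
#' @param config A [spot_config()] whose channels match.
#' @return A `spot_stack`.
#' @export
as_spot_stack <- function(frames, config) {
  stopifnot(inherits(config, "spot_config"))
  if (length(frames) != 3) stop("expected 3 pattern directions", call. = FALSE)
  shape <- NULL
  for (k in 1:3) {
    if (length(frames[[k]]) != 2) {
      stop(sprintf("direction %d: expected 2 phase frames, got %d",
                   k, length(frames[[k]])), call. = FALSE)
    }
    for (p in 1:2) {
      fr <- frames[[k]][[p]]
      if (!is.list(fr)) fr <- list(fr)
      if (length(fr) != length(config$channels)) {
        stop(sprintf("direction %d, phase %d: expected %d channel image(s)",
                     k, p, length(config$channels)), call. = FALSE)
      }
      names(fr) <- config$channels
      for (ch in config$channels) {
        if (is.null(fr[[ch]]) || !is.matrix(fr[[ch]])) {
          stop(sprintf("missing frame: direction %d, phase %d, channel %s",
                       k, p, ch), call. = FALSE)
        }
        if (is.null(shape)) shape <- dim(fr[[ch]])
        if (!all(dim(fr[[ch]]) == shape)) {
          stop("all frames must share one shape", call. = FALSE)
        }
      }
      frames[[k]][[p]] <- fr
    }
  }
  new_spot_stack(frames, config)
}

#' Write a single image as a normalized 32-bit float TIFF
#'
#' @param img Numeric matrix (NAs become 0 in the file).
#' @param path Output path.
#' @return Invisibly, list `(scale, offset)` restoring physical units as
#'   `pixel * scale + offset`.
#' @export
write_map_tiff <- function(img, path) {
  stopifnot(is.matrix(img))
  x <- img
  x[!is.finite(x)] <- 0
  lo <- min(0, min(x))
  scale <- max(1, max(x) - lo)
  suppressWarnings(tiff::writeTIFF((x - lo) / scale, path,
                                   bits.per.sample = 32L, compression = "none"))
  invisible(list(scale = scale, offset = lo))
}

#' Read an image written by [write_map_tiff()]
#'
#' @param path TIFF path.
#' @param scale,offset Normalization recorded at write time (e.g. from the
#'   reconstruction manifest).
#' @return Numeric matrix.
#' @export
read_map_tiff <- function(path, scale = 1, offset = 0) {
  tiff::readTIFF(path) * scale + offset
}

#' Store an affine transform as JSON
#'
#' Six numbers, row-major `[a11, a12, tx, a21, a22, ty]`, plus the
#' coordinate convention string.
#'
#' @param transform A `spot_affine`.
#' @param path Output path.
#' @export
write_affine_json <- function(transform, path) {
  tf <- as_affine(transform)
  jsonlite::write_json(
    list(matrix = as.vector(t(tf$matrix)),
         order = "row-major [a11, a12, tx, a21, a22, ty]",
         convention = "0-based pixel centers, x right, y down",
         rms = tf$rms, n_pairs = tf$n_pairs),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read an affine transform stored by [write_affine_json()]
#' @param path JSON path.
#' @return A `spot_affine`.
#' @export
read_affine_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(as.numeric(j$matrix), 2, 3, byrow = TRUE)
  tf <- new_affine(m)
  if (!is.null(j$rms) && length(j$rms) == 1 && is.finite(j$rms)) tf$rms <- j$rms
  tf
}

#' Store a set of group ellipses as JSON
#' @param ellipses List of [fit_group_ellipse()] results.
#' @param path Output path.
#' @export
write_ellipses_json <- function(ellipses, path) {
  jsonlite::write_json(
    lapply(ellipses, function(e) {
      list(label = e$label, mean = as.numeric(e$mean),
           cov = as.vector(e$cov), cov_order = "column-major 2x2", n = e$n)
    }),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read group ellipses stored by [write_ellipses_json()]
#' @param path JSON path.
#' @return List of `group_ellipse` objects.
#' @export
read_ellipses_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(j)), function(i) {
    structure(list(label = j$label[i], mean = as.numeric(j$mean[[i]]),
                   cov = matrix(as.numeric(j$cov[[i]]), 2, 2),
                   n = j$n[i]),
              class = "group_ellipse")
  })
}

#' Read a simulation scene description from YAML
#'
#' The file holds an `optical:` block (any [spot_config()] arguments) and an
#' `emitters:` list (any [dipole_emitters()] columns; `orientation_deg` may
#' be used instead of radians).
#'
#' @param path YAML file.
#' @return List with `config` (a `spot_config`) and `emitters`.
#' @export
read_scene_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(spot_config, y$optical %||% list())
  if (is.null(y$emitters)) stop("scene YAML has no `emitters` block", call. = FALSE)
  em <- dplyr::bind_rows(lapply(y$emitters, function(e) {
    # YAML 1.1 parses a bare `y` key as boolean TRUE; undo that
    names(e)[names(e) == "TRUE"] <- "y"
    tibble::as_tibble(e)
  }))
  if ("orientation_deg" %in% names(em)) {
    em$orientation <- em$orientation_deg * pi / 180
    em$orientation_deg <- NULL
  }
  args <- c(list(x = em$x, y = em$y), em[setdiff(names(em), c("x", "y"))])
  list(config = cfg, emitters = do.call(dipole_emitters, args))
}
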