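#' Render synthetic EMCCD movies from simulated emitter paths
#'
#' Realizes simulated paths as raw 16-bit image stacks at photophysical
#' fidelity. Every live emitter deposits `photons_per_strobe` expected photons
#' per frame, split equally over its strobe substep positions (so a moving
#' emitter is rendered with its true motion blur; an immobile one as a single
#' symmetric 2D Gaussian of sd `psf_sigma`), integrated over pixels. Poisson
#' photon noise and Poisson background are applied, EM gain is applied with
#' the EMCCD excess noise approximated by doubling the Poisson variance, and
#' Gaussian read noise is added.
#'
#' Coordinate convention: pixel centers at integer pixel coordinates, origin
#' at the top-left pixel center, x = column. The cell is placed at the field
#' center unless `origin_um` is given.
#'
#' @param paths List of `true_path` objects (see [simulate_trajectory()]),
#'   positions in the cell-local frame of `geometry`.
#' @param geometry The [cell_geometry()] the paths live in (maps local to
#'   world um).
#' @param config An [imaging_config()].
#' @param frame_count Number of frames to render (default: shortest path).
#' @param fov_px Integer length-2 field of view (columns, rows); default
#'   covers the cell with a 1-um margin.
#' @param origin_um World um coordinate of the top-left pixel center; default
#'   centers the field on the cell.
#' @param seed Optional integer seed.
#' @return A `spt_movie` object: `frames` (list of integer matrices, counts),
#'   `truth` (data.frame emitter_id, frame, x_um, y_um, z_um, species, alive,
#'   in field coordinates), `origin_um`, `config`.
#' @export
render_movie <- function(paths, geometry, config = imaging_config(),
                         frame_count = NULL, fov_px = NULL, origin_um = NULL,
                         seed = NULL) {
  if (config$pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  px <- config$pixel_size
  if (is.null(fov_px)) {
    span <- geometry$length + 2
    fov_px <- rep(as.integer(ceiling(span / px)), 2)
  }
  nx <- fov_px[1]; ny <- fov_px[2]
  if (is.null(origin_um)) {
    # field center at the cell center
    origin_um <- geometry$center - px * c((nx - 1) / 2, (ny - 1) / 2)
  }
  if (is.null(frame_count)) {
    frame_count <- if (length(paths)) min(vapply(paths, function(p)
      nrow(p$frames), numeric(1))) else 1L
  }

  n_sub <- if (length(paths)) nrow(paths[[1]]$substeps) / nrow(paths[[1]]$frames) else 1
  frames <- vector("list", frame_count)
  truth <- vector("list", length(paths))

  # per-frame expected photon images
  for (f in seq_len(frame_count)) {
    lambda <- matrix(config$background_rate, ny, nx)
    for (pi in seq_along(paths)) {
      path <- paths[[pi]]
      if (!path$alive[f]) next
      ns <- nrow(path$substeps) / nrow(path$frames)
      n_strobe <- max(1L, min(ns, as.integer(round(
        config$strobe_duration / config$frame_interval * ns))))
      idx <- (f - 1L) * ns + seq_len(n_strobe)
      sub <- path$substeps[idx, , drop = FALSE]
      world <- to_world(sub[, 1:2, drop = FALSE], geometry)
      xpix <- (world[, 1] - origin_um[1]) / px   # 0-based pixel coords
      ypix <- (world[, 2] - origin_um[2]) / px
      if (any(xpix < 0 | xpix > nx - 1 | ypix < 0 | ypix > ny - 1))
        stop("path leaves the field of view; enlarge fov_px", call. = FALSE)
      nph <- config$photons_per_strobe / n_strobe
      sig <- config$psf_sigma / px               # PSF sd in pixels
      for (k in seq_len(nrow(sub))) {
        lambda <- lambda + nph * gauss_pixel_image(xpix[k], ypix[k], sig, nx, ny)
      }
    }
    photons <- matrix(stats::rpois(nx * ny, lambda), ny, nx)
    counts <- config$em_gain * photons
    # EMCCD excess noise: double the Poisson variance
    counts <- counts + stats::rnorm(nx * ny, sd = config$em_gain * sqrt(photons))
    counts <- counts + stats::rnorm(nx * ny, sd = config$read_noise)
    frames[[f]] <- matrix(pmin(pmax(round(counts), 0), 65535L), ny, nx)
  }

  for (pi in seq_along(paths)) {
    path <- paths[[pi]]
    world <- to_world(path$frames[seq_len(frame_count), 1:2, drop = FALSE],
                      geometry)
    truth[[pi]] <- data.frame(
      emitter_id = pi, frame = seq_len(frame_count),
      x_um = world[, 1] - origin_um[1], y_um = world[, 2] - origin_um[2],
      z_um = path$frames[seq_len(frame_count), 3],
      species = path$species, alive = path$alive[seq_len(frame_count)])
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(emitter_id = integer(), frame = integer(), x_um = numeric(),
               y_um = numeric(), z_um = numeric(), species = character(),
               alive = logical())

  structure(list(frames = frames, truth = truth, origin_um = origin_um,
                 fov_px = c(nx, ny), config = config),
            class = "spt_movie")
}

# expected fraction of a unit-photon symmetric Gaussian (sd sig px) centered
# at 0-based pixel coords (x0, y0) falling in each pixel; ny x nx matrix
gauss_pixel_image <- function(x0, y0, sig, nx, ny) {
  cx <- diff(stats::pnorm((seq_len(nx + 1) - 1.5 - x0) / sig))
  cy <- diff(stats::pnorm((seq_len(ny + 1) - 1.5 - y0) / sig))
  outer(cy, cx)
}

#' @export
print.spt_movie <- function(x, ...) {
  cat(sprintf("Synthetic movie: %d frames of %d x %d px, %d emitter(s)\n",
              length(x$frames), x$fov_px[2], x$fov_px[1],
              length(unique(x$truth$emitter_id))))
  invisible(x)
}

#' Write a movie as a 16-bit multi-page TIFF (with ground-truth sidecars)
#'
#' @param movie An `spt_movie` from [render_movie()].
#' @param path Output TIFF path. The ground truth is written next to it as
#'   `<path>_truth.csv` and the configuration as `<path>_config.json`.
#' @return Invisibly, the TIFF path.
#' @export
write_movie_tiff <- function(movie, path) {
  pages <- lapply(movie$frames, function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, reduce = FALSE)
  utils::write.csv(movie$truth, paste0(path, "_truth.csv"), row.names = FALSE)
  meta <- unclass(movie$config)
  meta$origin_um <- movie$origin_um
  meta$fov_px <- movie$fov_px
  jsonlite::write_json(meta, paste0(path, "_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 16-bit multi-page TIFF movie
#'
#' @param path TIFF path as written by [write_movie_tiff()].
#' @return List of integer count matrices, one per frame.
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(m) round(m * 65535))
}
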