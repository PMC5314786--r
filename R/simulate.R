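#' Simulate confined Brownian motion of one emitter under stroboscopic imaging
#'
#' Simulates 3D Brownian increments at a substep resolution finer than the
#' frame interval, with specular reflection on the spherocylinder surface.
#' The per-frame reported position is the mean of the substep positions that
#' fall inside the strobe window at the start of each frame (motion blur of a
#' stroboscopically illuminated emitter).
#'
#' @param geometry A [cell_geometry()]. Ignored when `unconfined = TRUE`.
#' @param D Diffusion coefficient in um^2/s (>= 0).
#' @param n_frames Number of frames to simulate.
#' @param config An [imaging_config()].
#' @param substeps_per_frame Brownian substeps per frame (default 25, i.e.
#'   5 substeps inside a 1-ms strobe of a 5-ms frame).
#' @param seed Optional integer seed.
#' @param start Optional start position (x, y, z) in the cell-local frame;
#'   default: uniform inside the cell (origin if unconfined).
#' @param bleach_rate Photobleaching rate in 1/s; the emitter is alive until
#'   an exponential bleaching time (default 0, never bleaches).
#' @param unconfined If TRUE, free diffusion without boundaries.
#' @return A `true_path` object: list with `frames` (n_frames x 3 matrix of
#'   strobe-averaged positions, um, cell-local frame), `substeps` (all substep
#'   positions), `alive` (logical per frame), `D`, `species`.
#' @param species Ground-truth species label stored with the path.
#' @export
simulate_trajectory <- function(geometry, D, n_frames, config = imaging_config(),
                                substeps_per_frame = 25L, seed = NULL,
                                start = NULL, bleach_rate = 0,
                                species = NULL, unconfined = FALSE) {
  if (D < 0) stop("D must be >= 0", call. = FALSE)
  if (substeps_per_frame < 1) stop("substeps_per_frame must be >= 1", call. = FALSE)
  if (!unconfined) stopifnot(inherits(geometry, "cell_geometry"))
  if (!is.null(seed)) set.seed(seed)

  n_sub <- as.integer(substeps_per_frame)
  dt_sub <- config$frame_interval / n_sub
  n_total <- n_frames * n_sub
  n_strobe <- max(1L, min(n_sub, as.integer(round(
    config$strobe_duration / config$frame_interval * n_sub))))

  if (is.null(start)) {
    start <- if (unconfined) c(0, 0, 0) else drop(runif_spherocylinder(1, geometry))
  } else if (!unconfined && !inside_cell(matrix(start, 1), geometry)) {
    stop("start position outside the cell", call. = FALSE)
  }

  pos <- matrix(NA_real_, n_total, 3)
  if (D == 0) {
    pos[] <- rep(start, each = n_total)
  } else {
    sd_sub <- sqrt(2 * D * dt_sub)
    inc <- matrix(stats::rnorm(n_total * 3, sd = sd_sub), n_total, 3)
    if (unconfined) {
      pos <- sweep(apply(inc, 2, cumsum), 2, start, `+`)
      if (n_total == 1L) pos <- matrix(start + inc, 1, 3)
    } else {
      p <- start
      for (i in seq_len(n_total)) {
        p <- reflect_step(p, p + inc[i, ], geometry)
        pos[i, ] <- p
      }
    }
  }

  # strobe-averaged per-frame positions
  idx <- matrix(seq_len(n_total), nrow = n_sub)       # substeps by frame
  frames <- t(vapply(seq_len(n_frames), function(f) {
    colMeans(pos[idx[seq_len(n_strobe), f], , drop = FALSE])
  }, numeric(3)))
  colnames(frames) <- c("x", "y", "z")

  alive <- rep(TRUE, n_frames)
  if (bleach_rate > 0) {
    t_bleach <- stats::rexp(1, bleach_rate)
    alive <- (seq_len(n_frames) - 1) * config$frame_interval < t_bleach
  }

  structure(list(frames = frames, substeps = pos, alive = alive, D = D,
                 species = species %||% if (D == 0) "immobile" else "mobile",
                 geometry = if (unconfined) NULL else geometry,
                 config = config),
            class = "true_path")
}

#' @export
print.true_path <- function(x, ...) {
  cat(sprintf("Simulated path: %d frames, D = %g um^2/s, species '%s'\n",
              nrow(x$frames), x$D, x$species))
  invisible(x)
}

#' Simulate localization tables for a population of cells (geometric path)
#'
#' Fast synthetic-data path used by the simulation-based calibration: true
#' strobe-averaged positions are projected onto the image plane (x, y) and
#' independent Gaussian per-axis localization error `config$loc_error_axis`
#' is added; no movie rendering. The number of emitters per cell is Poisson.
#'
#' @param geometry A [cell_geometry()] (same shape reused for every cell).
#' @param species_mix Two-column matrix or data.frame `(D, weight)`; weights
#'   must sum to 1.
#' @param mean_emitters_per_cell Poisson mean of emitters per cell (default 1.5).
#' @param n_cells Number of cells (default 500).
#' @param n_frames Frames each emitter is simulated for (default 10).
#' @param config An [imaging_config()].
#' @param substeps_per_frame See [simulate_trajectory()].
#' @param seed Optional integer seed.
#' @param unconfined If TRUE, skip confinement (testing aid).
#' @return A data.frame with columns `cell_id, emitter_id, species, D_true,
#'   frame, x_um, y_um, true_x_um, true_y_um, true_z_um`. Localizations are in
#'   the cell-local frame of each cell.
#' @export
simulate_localized_tracks <- function(geometry, species_mix,
                                      mean_emitters_per_cell = 1.5,
                                      n_cells = 500, n_frames = 10,
                                      config = imaging_config(),
                                      substeps_per_frame = 25L,
                                      seed = NULL, unconfined = FALSE) {
  species_mix <- unname(as.matrix(species_mix))
  if (nrow(species_mix) == 0) stop("species_mix must be non-empty", call. = FALSE)
  if (abs(sum(species_mix[, 2]) - 1) > 1e-8)
    stop("species weights must sum to 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  s <- config$loc_error_axis
  out <- vector("list", n_cells)
  emitter_counter <- 0L
  for (ci in seq_len(n_cells)) {
    k <- stats::rpois(1, mean_emitters_per_cell)
    if (k == 0) next
    rows <- vector("list", k)
    for (ei in seq_len(k)) {
      sp <- sample.int(nrow(species_mix), 1, prob = species_mix[, 2])
      Dk <- species_mix[sp, 1]
      path <- simulate_trajectory(geometry, Dk, n_frames, config,
                                  substeps_per_frame, unconfined = unconfined)
      emitter_counter <- emitter_counter + 1L
      xy <- unname(path$frames[, 1:2, drop = FALSE])
      rows[[ei]] <- data.frame(
        cell_id = ci, emitter_id = emitter_counter,
        species = paste0("sp", sp), D_true = Dk,
        frame = seq_len(n_frames),
        x_um = xy[, 1] + stats::rnorm(n_frames, sd = s),
        y_um = xy[, 2] + stats::rnorm(n_frames, sd = s),
        true_x_um = xy[, 1], true_y_um = xy[, 2],
        true_z_um = path$frames[, 3])
    }
    out[[ci]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(cell_id = integer(), emitter_id = integer(),
                                      species = character(), D_true = numeric(),
                                      frame = integer(), x_um = numeric(),
                                      y_um = numeric(), true_x_um = numeric(),
                                      true_y_um = numeric(), true_z_um = numeric())
  rownames(out) <- NULL
  out
}

#' Simulate quantized single-cell photobleaching traces
#'
#' Each of `molecules_per_cell` fluorophores bleaches at an independent
#' exponential time; the cell trace is the number of surviving fluorophores
#' times the unitary intensity, plus Gaussian noise.
#'
#' @param n_cells Number of cells.
#' @param molecules_per_cell Integer (scalar or length-`n_cells` vector) true
#'   molecule count per cell.
#' @param unitary_intensity Intensity of one fluorophore (arbitrary counts).
#' @param bleach_rate Bleaching rate in 1/s (lifetime = 1/bleach_rate).
#' @param noise_sd Gaussian noise sd added to each trace point (counts).
#' @param frame_interval Trace sampling interval in seconds (default 0.05).
#' @param duration Trace duration in seconds (default 5 mean lifetimes).
#' @param seed Optional integer seed.
#' @return A `bleach_traces` object: `time` (seconds), `traces`
#'   (n_frames x n_cells matrix), `true_counts`, `unitary_intensity`,
#'   `bleach_rate`.
#' @export
simulate_bleach_traces <- function(n_cells, molecules_per_cell,
                                   unitary_intensity, bleach_rate,
                                   noise_sd, frame_interval = 0.05,
                                   duration = NULL, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(molecules_per_cell < 0))
    stop("molecules_per_cell must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  counts <- rep_len(as.integer(molecules_per_cell), n_cells)
  if (is.null(duration)) duration <- 5 / bleach_rate
  tt <- seq(0, duration, by = frame_interval)
  traces <- matrix(0, length(tt), n_cells)
  for (ci in seq_len(n_cells)) {
    n <- counts[ci]
    alive <- if (n > 0) {
      tb <- stats::rexp(n, bleach_rate)
      vapply(tt, function(t0) sum(tb > t0), numeric(1))
    } else rep(0, length(tt))
    traces[, ci] <- unitary_intensity * alive
  }
  if (noise_sd > 0) traces <- traces + stats::rnorm(length(traces), sd = noise_sd)
  structure(list(time = tt, traces = traces, true_counts = counts,
                 unitary_intensity = unitary_intensity,
                 bleach_rate = bleach_rate, noise_sd = noise_sd),
            class = "bleach_traces")
}

#' @export
print.bleach_traces <- function(x, ...) {
  cat(sprintf("%d photobleaching traces, %d frames, u = %g, lifetime = %g s\n",
              ncol(x$traces), nrow(x$traces), x$unitary_intensity,
              1 / x$bleach_rate))
  invisible(x)
}

#' Sample a 3D spatial point pattern inside a cell
#'
#' `uniform` samples uniformly in the spherocylinder volume. `periphery_biased`
#' weights points by `(rho / r_local)^bias`, where rho is the distance from
#' the midline and `r_local` the local half-width, pushing density toward the
#' membrane (bias = 0 reduces to uniform).
#'
#' @param geometry A [cell_geometry()].
#' @param n_points Number of points (>= 1).
#' @param mode `"uniform"` or `"periphery_biased"`.
#' @param bias Radial weight exponent for the biased mode (default 2).
#' @param seed Optional integer seed.
#' @return A `spatial_pattern` object: `points` (n x 3 matrix, cell-local um),
#'   `mode`, `bias`, `geometry`.
#' @export
sample_spatial_pattern <- function(geometry, n_points,
                                   mode = c("uniform", "periphery_biased"),
                                   bias = 2, seed = NULL) {
  if (n_points < 1) stop("n_points must be >= 1", call. = FALSE)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  a <- cyl_half_length(geometry)
  r <- geometry$radius
  if (mode == "uniform" || bias == 0) {
    pts <- runif_spherocylinder(n_points, geometry)
  } else {
    pts <- matrix(NA_real_, n_points, 3)
    got <- 0L
    while (got < n_points) {
      cand <- runif_spherocylinder(2L * (n_points - got) + 64L, geometry)
      xc <- pmin(pmax(cand[, 1], -a), a)
      rho <- sqrt((cand[, 1] - xc)^2 + cand[, 2]^2 + cand[, 3]^2)
      rloc <- sqrt(pmax(r^2 - (abs(cand[, 1]) - a)^2 * (abs(cand[, 1]) > a), 0))
      rloc[abs(cand[, 1]) <= a] <- r
      w <- (rho / pmax(rloc, .Machine$double.eps))^bias
      keep <- which(stats::runif(nrow(cand)) < pmin(w, 1))
      if (length(keep)) {
        take <- keep[seq_len(min(length(keep), n_points - got))]
        pts[(got + 1L):(got + length(take)), ] <- cand[take, , drop = FALSE]
        got <- got + length(take)
      }
    }
    colnames(pts) <- c("x", "y", "z")
  }
  structure(list(points = pts, mode = mode,
                 bias = if (mode == "uniform") 0 else bias,
                 geometry = geometry),
            class = "spatial_pattern")
}

#' @export
print.spatial_pattern <- function(x, ...) {
  cat(sprintf("Spatial pattern: %d points, mode '%s' (bias %g)\n",
              nrow(x$points), x$mode, x$bias))
  invisible(x)
}
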