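#' Simulation-based calibration of apparent to accurate diffusion coefficients
#'
#' The apparent diffusion coefficient of a fast molecule in a bacterium is
#' biased by cellular confinement, stroboscopic motion blur, localization
#' error and the finite linking window. This routine quantifies those biases
#' by running the full geometric pipeline
#' (simulate -> localize -> link -> apparent D) for a grid of true diffusion
#' coefficients, recording the mean apparent D of the simulated (mobile)
#' species, and fitting a monotone interpolant. The inverse map turns a
#' measured apparent D into an accurate D with an uncertainty interval
#' propagated from the replicate scatter and the measurement error.
#'
#' @param true_D_grid Increasing vector of true diffusion coefficients
#'   (um^2/s).
#' @param geometry A [cell_geometry()].
#' @param config An [imaging_config()].
#' @param n_cells Cells per simulation run (default 500).
#' @param mean_per_cell Mean emitters per cell (default 1.5).
#' @param replicates Replicate runs per grid point (default 2).
#' @param n_frames Frames per emitter (default 10).
#' @param tracking A [tracking_config()].
#' @param substeps_per_frame See [simulate_trajectory()].
#' @param seed Integer seed (replicate r at grid point i uses a distinct
#'   stream derived from it).
#' @return An `spt_calibration` object.
#' @export
calibrate <- function(true_D_grid, geometry, config = imaging_config(),
                      n_cells = 500, mean_per_cell = 1.5, replicates = 2,
                      n_frames = 10, tracking = tracking_config(),
                      substeps_per_frame = 25L, seed = 1) {
  if (is.unsorted(true_D_grid, strictly = TRUE))
    stop("true_D_grid must be strictly increasing", call. = FALSE)
  app <- matrix(NA_real_, length(true_D_grid), replicates)
  for (i in seq_along(true_D_grid)) {
    for (r in seq_len(replicates)) {
      app[i, r] <- apparent_of_true(true_D_grid[i], geometry, config,
                                    n_cells, mean_per_cell, n_frames,
                                    tracking, substeps_per_frame,
                                    seed = seed + 7919L * (i - 1L) + 131L * r)
    }
  }
  m <- rowMeans(app)
  s <- apply(app, 1, stats::sd)
  if (is.unsorted(m, strictly = TRUE)) {
    stop(sprintf(paste0("apparent D is not strictly increasing along the ",
                        "grid; means: %s (increase n_cells or replicates)"),
                 paste(signif(m, 3), collapse = ", ")), call. = FALSE)
  }
  forward <- stats::splinefun(true_D_grid, m, method = "hyman")
  structure(list(true_D = true_D_grid, apparent_mean = m, apparent_sd = s,
                 replicates = replicates, forward = forward,
                 geometry = geometry, config = config, n_cells = n_cells,
                 mean_per_cell = mean_per_cell),
            class = "spt_calibration")
}

# one full geometric pipeline run -> mean apparent D of the mobile species
apparent_of_true <- function(D_true, geometry, config, n_cells, mean_per_cell,
                             n_frames, tracking, substeps_per_frame, seed,
                             unconfined = FALSE) {
  loc <- simulate_localized_tracks(geometry, cbind(D_true, 1),
                                   mean_emitters_per_cell = mean_per_cell,
                                   n_cells = n_cells, n_frames = n_frames,
                                   config = config,
                                   substeps_per_frame = substeps_per_frame,
                                   seed = seed, unconfined = unconfined)
  tracks <- link(loc[, c("cell_id", "frame", "x_um", "y_um")], tracking)
  d <- apparent_D(tracks, n_steps = tracking$min_steps_for_D,
                  dt = config$frame_interval)
  if (nrow(d) < 10) stop("too few trajectories survived linking", call. = FALSE)
  # the simulation holds a single mobile species: its mean apparent D is the
  # maximum-likelihood gamma mean
  mean(d$D_app)
}

#' @export
print.spt_calibration <- function(x, digits = 3, ...) {
  cat("Apparent-vs-true diffusion calibration\n")
  tab <- data.frame(true_D = x$true_D,
                    apparent = signif(x$apparent_mean, digits),
                    sd = signif(x$apparent_sd, digits))
  print(tab, row.names = FALSE)
  cat(sprintf("(%d cells, %g emitters/cell, %d replicates per point)\n",
              x$n_cells, x$mean_per_cell, x$replicates))
  invisible(x)
}

#' Invert a calibration: accurate D from a measured apparent D
#'
#' @param object An `spt_calibration`.
#' @param apparent_D Measured apparent diffusion coefficient(s), um^2/s.
#' @param error Standard error(s) of the measured apparent D (default 0).
#' @param ... Unused.
#' @return Data frame `apparent_D, accurate_D, lower, upper`; the interval is
#'   the quadrature sum of the replicate sd (interpolated along the grid) and
#'   the measurement error, propagated through the local slope.
#' @export
predict.spt_calibration <- function(object, apparent_D, error = 0, ...) {
  rng <- range(object$apparent_mean)
  sd_fun <- stats::approxfun(object$true_D, object$apparent_sd, rule = 2)
  out <- mapply(function(a, e) {
    if (a < rng[1] || a > rng[2])
      stop(sprintf("apparent D %.3g outside calibrated range [%.3g, %.3g]",
                   a, rng[1], rng[2]), call. = FALSE)
    root <- stats::uniroot(function(Dt) object$forward(Dt) - a,
                           range(object$true_D), tol = 1e-9)$root
    slope <- object$forward(root, deriv = 1)
    tot <- sqrt(sd_fun(root)^2 + e^2) / max(slope, 1e-9)
    c(accurate = root, lower = root - tot, upper = root + tot)
  }, apparent_D, error)
  data.frame(apparent_D = apparent_D, accurate_D = out["accurate", ],
             lower = out["lower", ], upper = out["upper", ])
}

#' @export
plot.spt_calibration <- function(x, xlab = expression(true ~ D ~ (mu * m^2 / s)),
                                 ylab = expression(apparent ~ D ~ (mu * m^2 / s)),
                                 ...) {
  graphics::plot(x$true_D, x$apparent_mean, pch = 19, xlab = xlab,
                 ylab = ylab, ...)
  graphics::arrows(x$true_D, x$apparent_mean - x$apparent_sd,
                   x$true_D, x$apparent_mean + x$apparent_sd,
                   angle = 90, code = 3, length = 0.03)
  xs <- seq(min(x$true_D), max(x$true_D), length.out = 200)
  graphics::lines(xs, x$forward(xs))
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}
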