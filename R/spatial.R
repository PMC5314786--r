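#' Normalize localizations into the unit-cell frame
#'
#' Positions (world um) are expressed relative to the cell midline:
#' `x_norm` is the absolute distance along the midline from mid-cell,
#' normalized so 0 = mid-cell and 1 = pole tip; `y_norm` is the absolute
#' perpendicular distance to the midline divided by the local half-width
#' (the cell radius on the cylindrical part, the hemispherical cap profile
#' `sqrt(r^2 - (|x| - a)^2)` near the poles), so 0 = midline and 1 = outline.
#' Points outside the outline by more than `tol` are dropped and counted.
#'
#' @param points Matrix or data.frame with columns x, y (world um).
#' @param geometry A [cell_geometry()].
#' @param tol Tolerance outside the outline in um (default 0.05).
#' @return Data frame `x_norm, y_norm` (both in `[0, 1]`) with attribute
#'   `n_dropped`.
#' @export
normalize_position <- function(points, geometry, tol = 0.05) {
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  loc <- to_local(p, geometry)
  a <- cyl_half_length(geometry)
  r <- geometry$radius
  L2 <- geometry$length / 2
  ax <- abs(loc[, 1]); ay <- abs(loc[, 2])
  halfw <- ifelse(ax <= a, r, sqrt(pmax(r^2 - (ax - a)^2, 0)))
  # pole tips have zero half-width; a point there is on the outline
  y_norm <- ifelse(halfw > 0, ay / halfw, ifelse(ay <= tol, 1, Inf))
  x_norm <- ax / L2
  keep <- x_norm <= 1 + tol / L2 & y_norm <= 1 + tol / r
  out <- data.frame(x_norm = pmin(x_norm[keep], 1),
                    y_norm = pmin(y_norm[keep], 1))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Analytic short-axis density of a uniform distribution in a cylinder
#'
#' Probability density of the absolute radial coordinate rho of points
#' distributed uniformly in a cylindrical volume, projected onto one
#' transverse axis, for the unit cell (r = 1):
#' `pdf(rho) = 4 * sqrt(max(1 - rho^2, 0)) / pi`.
#'
#' @param rho Normalized short-axis coordinate(s) in `[0, 1]`.
#' @return Density value(s); `uniform_pdf(0) = 4/pi`.
#' @export
uniform_pdf <- function(rho) {
  if (any(rho < 0 | rho > 1)) stop("rho must be in [0, 1]", call. = FALSE)
  4 * sqrt(pmax(1 - rho^2, 0)) / pi
}

# mass of the uniform-cylinder density above cutoff c
uniform_periphery_mass <- function(c) {
  stats::integrate(uniform_pdf, c, 1, rel.tol = 1e-10)$value
}

#' Periphery/mid-cell enrichment relative to the uniform-cylinder reference
#'
#' Splits unit-cell positions at a short-axis cutoff into periphery
#' (`y_norm >= cutoff`) and mid-cell (`y_norm < cutoff`) regions, compares
#' the observed occupancy of each region with the analytic uniform-cylinder
#' expectation, and reports the percent enrichment
#' `(observed / uniform - 1) * 100` with a seeded bootstrap confidence
#' interval.
#'
#' @param positions Data frame with a `y_norm` column (e.g. from
#'   [normalize_position()]); at least 100 rows.
#' @param cutoff Short-axis boundary between mid-cell and periphery
#'   (default 0.5).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Bootstrap seed (default 1).
#' @return A `spatial_summary` object: observed and uniform fractions,
#'   `enrichment_periphery` and `enrichment_midcell` (percent, with CI),
#'   histogram density of `y_norm`.
#' @export
enrichment <- function(positions, cutoff = 0.5, n_boot = 1000, conf = 0.95,
                       seed = 1) {
  y <- positions$y_norm
  if (length(y) < 100) stop("need at least 100 positions", call. = FALSE)
  u_per <- uniform_periphery_mass(cutoff)
  u_mid <- 1 - u_per
  obs_per <- mean(y >= cutoff)
  obs_mid <- 1 - obs_per
  enr <- function(op) c(periphery = (op / u_per - 1) * 100,
                        midcell = ((1 - op) / u_mid - 1) * 100)
  e <- enr(obs_per)
  set.seed(seed)
  bo <- replicate(n_boot, {
    yy <- y[sample.int(length(y), replace = TRUE)]
    enr(mean(yy >= cutoff))
  })
  alpha <- (1 - conf) / 2
  ci <- apply(bo, 1, stats::quantile, probs = c(alpha, 1 - alpha))
  flagged <- obs_per %in% c(0, 1)
  h <- graphics::hist(y, breaks = seq(0, 1, by = 0.05), plot = FALSE)
  structure(list(cutoff = cutoff, n = length(y),
                 observed_periphery = obs_per, observed_midcell = obs_mid,
                 uniform_periphery = u_per, uniform_midcell = u_mid,
                 enrichment_periphery = unname(e["periphery"]),
                 enrichment_midcell = unname(e["midcell"]),
                 ci_periphery = unname(ci[, "periphery"]),
                 ci_midcell = unname(ci[, "midcell"]),
                 empty_region = flagged,
                 density = data.frame(mid = h$mids, density = h$density)),
            class = "spatial_summary")
}

#' @export
print.spatial_summary <- function(x, ...) {
  cat(sprintf("Short-axis spatial summary (cutoff %.2f, n = %d)\n",
              x$cutoff, x$n))
  cat(sprintf("  periphery: observed %.3f vs uniform %.3f -> %+.1f%% [%.1f, %.1f]\n",
              x$observed_periphery, x$uniform_periphery,
              x$enrichment_periphery, x$ci_periphery[1], x$ci_periphery[2]))
  cat(sprintf("  mid-cell : observed %.3f vs uniform %.3f -> %+.1f%% [%.1f, %.1f]\n",
              x$observed_midcell, x$uniform_midcell,
              x$enrichment_midcell, x$ci_midcell[1], x$ci_midcell[2]))
  if (x$empty_region) cat("  warning: one region is empty\n")
  invisible(x)
}

#' @export
plot.spatial_summary <- function(x, xlab = "normalized short-axis position",
                                 ylab = "probability density", ...) {
  graphics::plot(x$density$mid, x$density$density, type = "h", lwd = 6,
                 lend = 1, col = "grey70", xlab = xlab, ylab = ylab,
                 ylim = c(0, max(x$density$density, 4 / pi) * 1.1), ...)
  rho <- seq(0, 1, length.out = 200)
  graphics::lines(rho, uniform_pdf(rho), lty = 3, lwd = 2)
  graphics::abline(v = x$cutoff, col = 2, lty = 2)
  invisible(x)
}

#' Bin unit-cell positions by cell length
#'
#' Cells are partitioned into short (single nucleoid) and long (duplicated
#' nucleoid) classes; positions of cells outside both bins are excluded and
#' counted. Per-bin short-axis summaries and a 2D unit-cell histogram are
#' returned.
#'
#' @param positions Data frame with `x_norm`, `y_norm` and `cell_len_um`.
#' @param short_range Short-cell length bin in um (default `c(1.7, 2.9)`).
#' @param long_range Long-cell length bin in um (default `c(3.1, 4.3)`).
#' @param cutoff Passed to [enrichment()].
#' @param nbins_2d Bins per axis for the 2D histogram (default 20).
#' @param ... Passed to [enrichment()].
#' @return List with elements `short` and `long`, each containing `summary`
#'   (a `spatial_summary` or NULL if under 100 positions), `hist2d`, `n`;
#'   plus `n_excluded` and a `bin` vector aligned with `positions`.
#' @export
bin_by_length <- function(positions, short_range = c(1.7, 2.9),
                          long_range = c(3.1, 4.3), cutoff = 0.5,
                          nbins_2d = 20, ...) {
  len <- positions$cell_len_um
  bin <- rep(NA_character_, nrow(positions))
  bin[len >= short_range[1] & len <= short_range[2]] <- "short"
  bin[len >= long_range[1] & len <= long_range[2]] <- "long"
  res <- lapply(c(short = "short", long = "long"), function(b) {
    p <- positions[!is.na(bin) & bin == b, , drop = FALSE]
    s <- if (nrow(p) >= 100) enrichment(p, cutoff = cutoff, ...) else NULL
    brk <- seq(0, 1, length.out = nbins_2d + 1)
    h2 <- if (nrow(p)) table(cut(p$x_norm, brk, include.lowest = TRUE),
                             cut(p$y_norm, brk, include.lowest = TRUE))
          else NULL
    list(summary = s, hist2d = h2, n = nrow(p))
  })
  c(res, list(n_excluded = sum(is.na(bin)), bin = bin))
}

#' Split unit-cell positions into slow and fast diffusing sets
#'
#' Joins positions with per-trajectory apparent diffusion coefficients and
#' partitions them at the mobility threshold (slow: `D_app < threshold`).
#'
#' @param positions Data frame with a `traj_id` column.
#' @param D_estimates Data frame `traj_id, D_app` (from [apparent_D()]).
#' @param threshold Mobility threshold in um^2/s (default 1).
#' @return List `slow`, `fast` (position subsets), `fraction_slow`.
#' @export
slow_fast_split <- function(positions, D_estimates, threshold = 1) {
  d <- D_estimates$D_app[match(positions$traj_id, D_estimates$traj_id)]
  if (any(is.na(d)))
    stop("every position needs a trajectory D_app", call. = FALSE)
  slow <- d < threshold
  list(slow = positions[slow, , drop = FALSE],
       fast = positions[!slow, , drop = FALSE],
       fraction_slow = mean(slow))
}
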