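#' Diffusion-based tRNA cycle budget
#'
#' Back-of-the-envelope arithmetic testing whether a diffusion-based tRNA
#' cycle (tRNA alternating between ribosome-bound translation and free
#' diffusive search) can sustain protein synthesis. With two tRNA molecules
#' resident at every ribosome, `bound = sites * ribosomes` tRNAs are bound
#' and the rest of the pool is searching. Each ribosome visit lasts
#' `sites * aa_time`; dividing by the (rounded) bound fraction gives the full
#' cycle time, and the remainder is the search-and-recharge time. The time to
#' explore the cell is from `MSD(t) = 6*D*t` reaching `msd_target_um2`.
#'
#' @param aa_time Translation time per amino acid, s (default 0.050).
#' @param ribosomes Ribosomes per cell (default 50000).
#' @param pool Total tRNA pool per cell (default 375000).
#' @param sites tRNA sites occupied per ribosome (default 2).
#' @param bound_fraction_rounded Rounded ribosome-bound tRNA fraction used
#'   for the cycle arithmetic (default 0.25).
#' @param D Free-diffusion coefficient, um^2/s (default 8); must be > 0.
#' @param cell_dims Cell dimensions (length, diameter) in um (default 3 x 1).
#' @param msd_target_um2 MSD (um^2) taken to span the cell; default the
#'   numeric value of the long axis (3 um -> 3 um^2).
#' @return A `cycle_budget` object (list of all quantities).
#' @examples
#' cycle_budget()  # bound 1e5, searching 2.75e5, cycle 0.4 s
#' @export
cycle_budget <- function(aa_time = 0.050, ribosomes = 50000, pool = 375000,
                         sites = 2, bound_fraction_rounded = 0.25, D = 8,
                         cell_dims = c(3, 1), msd_target_um2 = NULL) {
  if (D <= 0) stop("exploration time undefined for D <= 0", call. = FALSE)
  bound <- sites * ribosomes
  if (pool < bound) stop("pool must be >= sites * ribosomes", call. = FALSE)
  searching <- pool - bound
  bound_fraction <- bound / pool
  bound_time <- sites * aa_time
  cycle_time <- bound_time / bound_fraction_rounded
  search_time <- cycle_time - bound_time
  if (is.null(msd_target_um2)) msd_target_um2 <- max(cell_dims)
  exploration_time <- msd_target_um2 / (6 * D)
  structure(list(aa_time = aa_time, ribosomes = ribosomes, pool = pool,
                 sites = sites, bound = bound, searching = searching,
                 bound_fraction = bound_fraction,
                 bound_fraction_rounded = bound_fraction_rounded,
                 bound_time = bound_time, cycle_time = cycle_time,
                 search_time = search_time, D = D, cell_dims = cell_dims,
                 msd_target_um2 = msd_target_um2,
                 exploration_time = exploration_time),
            class = "cycle_budget")
}

#' @export
print.cycle_budget <- function(x, ...) {
  cat("Diffusion-based tRNA cycle budget\n")
  cat(sprintf("  ribosome-bound tRNA : %d (%.0f%% of pool %d)\n",
              x$bound, 100 * x$bound_fraction, x$pool))
  cat(sprintf("  searching tRNA      : %d\n", x$searching))
  cat(sprintf("  bound time          : %.0f ms (%d sites x %.0f ms/aa)\n",
              1e3 * x$bound_time, x$sites, 1e3 * x$aa_time))
  cat(sprintf("  full cycle          : %.0f ms, search %.0f ms\n",
              1e3 * x$cycle_time, 1e3 * x$search_time))
  cat(sprintf("  cell exploration    : %.1f ms (MSD %g um^2 at D = %g um^2/s)\n",
              1e3 * x$exploration_time, x$msd_target_um2, x$D))
  invisible(x)
}
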