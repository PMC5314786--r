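# shared fixtures: the canonical 3 x 1 um cell and acquisition settings
ecoli_cell <- function() cell_geometry(length = 3, radius = 0.5)

strobe_config <- function(...) imaging_config(...)

# point-sampled symmetric Gaussian frame (matches the fit_spot model exactly)
gaussian_frame <- function(nx, ny, x0, y0, sd_px, amplitude = 1000, bg = 10) {
  gx <- matrix(rep(0:(nx - 1), each = ny), ny)
  gy <- matrix(rep(0:(ny - 1), times = nx), ny)
  amplitude * exp(-((gx - x0)^2 + (gy - y0)^2) / (2 * sd_px^2)) + bg
}

# CDF of the uniform-cylinder short-axis density, for KS tests
uniform_cdf <- function(rho) (2 / pi) * (asin(rho) + rho * sqrt(1 - rho^2))

# simulate the immobile (fixed-cell) geometric pipeline once per session
fixed_cell_Dapp <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      loc <- simulate_localized_tracks(ecoli_cell(), cbind(0, 1),
                                       mean_emitters_per_cell = 1.5,
                                       n_cells = 700, n_frames = 6,
                                       config = strobe_config(), seed = 420)
      tracks <- link(loc[, c("cell_id", "frame", "x_um", "y_um")])
      cache <<- apparent_D(tracks, dt = 0.005)
    }
    cache
  }
})
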