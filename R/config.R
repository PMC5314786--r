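#' Imaging configuration
#'
#' Bundles the acquisition parameters of a stroboscopic single-molecule
#' tracking experiment: a short excitation pulse (`strobe_duration`) inside a
#' longer camera exposure (`frame_interval`) suppresses motion blur of fast
#' molecules, while the EMCCD photon/noise model determines localization
#' precision.
#'
#' The default pixel size is 0.67/7 um (a 7-pixel window spans ~0.67 um).
#' `loc_error_axis` is the per-axis single-localization error s in um; the
#' conventional localization precision is sigma = 2 s (see
#' [precision_from_fixed()]).
#'
#' @param frame_interval Frame-to-frame interval Delta-t in seconds.
#' @param strobe_duration Excitation pulse length in seconds (at frame start).
#' @param pixel_size Camera pixel size in um/pixel.
#' @param psf_sigma Standard deviation of the (symmetric) PSF in um.
#' @param photons_per_strobe Expected detected photons per emitter per strobe.
#' @param background_rate Expected background photons per pixel per frame.
#' @param em_gain Camera counts per detected photon.
#' @param read_noise Gaussian read noise, counts RMS.
#' @param loc_error_axis Per-axis single-localization error s in um.
#' @return An object of class `imaging_config` (a validated list).
#' @examples
#' cfg <- imaging_config()
#' cfg$frame_interval
#' @export
imaging_config <- function(frame_interval = 0.005,
                           strobe_duration = 0.001,
                           pixel_size = 0.67 / 7,
                           psf_sigma = 0.13,
                           photons_per_strobe = 120,
                           background_rate = 2,
                           em_gain = 20,
                           read_noise = 10,
                           loc_error_axis = 0.04) {
  cfg <- list(frame_interval = frame_interval,
              strobe_duration = strobe_duration,
              pixel_size = pixel_size,
              psf_sigma = psf_sigma,
              photons_per_strobe = photons_per_strobe,
              background_rate = background_rate,
              em_gain = em_gain,
              read_noise = read_noise,
              loc_error_axis = loc_error_axis)
  validate_imaging_config(cfg)
  class(cfg) <- "imaging_config"
  cfg
}

validate_imaging_config <- function(cfg) {
  stopifnot(is.numeric(cfg$frame_interval), cfg$frame_interval > 0)
  if (cfg$strobe_duration > cfg$frame_interval)
    stop("strobe_duration must not exceed frame_interval", call. = FALSE)
  if (cfg$pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  rates <- c(cfg$photons_per_strobe, cfg$background_rate, cfg$em_gain,
             cfg$read_noise, cfg$loc_error_axis, cfg$strobe_duration)
  if (any(rates < 0)) stop("all rates must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' @export
print.imaging_config <- function(x, ...) {
  cat("Imaging configuration\n")
  cat(sprintf("  frame interval : %g ms\n", 1e3 * x$frame_interval))
  cat(sprintf("  strobe         : %g ms\n", 1e3 * x$strobe_duration))
  cat(sprintf("  pixel size     : %.4f um\n", x$pixel_size))
  cat(sprintf("  PSF sigma      : %g um\n", x$psf_sigma))
  cat(sprintf("  photons/strobe : %g, background %g ph/px/frame\n",
              x$photons_per_strobe, x$background_rate))
  cat(sprintf("  EM gain %g counts/photon, read noise %g counts RMS\n",
              x$em_gain, x$read_noise))
  cat(sprintf("  per-axis localization error s = %g um\n", x$loc_error_axis))
  invisible(x)
}

#' Tracking (linking) configuration
#'
#' @param max_link_distance Maximum frame-to-frame displacement in um for two
#'   localizations to be linked (default 0.67 um, i.e. a 7-pixel window).
#' @param memory_frames Number of frames a disappeared spot is remembered
#'   before its track is terminated (default 1).
#' @param min_steps_for_D Minimum number of single-frame steps a trajectory
#'   needs before an apparent diffusion coefficient is estimated (default 4).
#' @param gap_distance_factor Multiplier on `max_link_distance` allowed for a
#'   displacement bridging a one-frame gap; displacement variance grows with
#'   lag, so the default is sqrt(2).
#' @return An object of class `tracking_config`.
#' @export
tracking_config <- function(max_link_distance = 0.67,
                            memory_frames = 1,
                            min_steps_for_D = 4,
                            gap_distance_factor = sqrt(2)) {
  if (max_link_distance <= 0) stop("max_link_distance must be > 0", call. = FALSE)
  if (memory_frames < 0) stop("memory_frames must be >= 0", call. = FALSE)
  cfg <- list(max_link_distance = max_link_distance,
              memory_frames = as.integer(memory_frames),
              min_steps_for_D = as.integer(min_steps_for_D),
              gap_distance_factor = gap_distance_factor)
  class(cfg) <- "tracking_config"
  cfg
}

#' @export
print.tracking_config <- function(x, ...) {
  cat(sprintf("Tracking: window %g um, memory %d frame(s), >= %d steps for D\n",
              x$max_link_distance, x$memory_frames, x$min_steps_for_D))
  invisible(x)
}
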