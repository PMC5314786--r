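#' Default pipeline configuration
#'
#' Returns the demo configuration as a nested list; [run_pipeline()] accepts
#' the same structure from a YAML file. All seeds are recorded in the output
#' manifest and every artifact carries the configuration hash.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(out_dir = "rodspt_out", seed = 1) {
  list(
    seed = seed,
    out_dir = out_dir,
    geometry = list(length = 3, radius = 0.5),
    imaging = list(),    # overrides for imaging_config()
    tracking = list(),   # overrides for tracking_config()
    analysis = list(mobility_threshold = 1, n_steps = 4,
                    periphery_cutoff = 0.5),
    stages = list(simulate = TRUE, render = FALSE, localize = FALSE,
                  track = TRUE, diffuse = TRUE, calibrate = FALSE,
                  count = TRUE, spatial = TRUE),
    simulate = list(species = list(list(D = 8.1, weight = 0.88),
                                   list(D = 0.32, weight = 0.12)),
                    n_cells = 120, mean_per_cell = 1.5, n_frames = 10),
    count = list(n_cells = 60, molecules_per_cell = 3,
                 unitary_intensity = 8.7, noise_sd = 2.4,
                 bleach_lifetime_s = 3.4, frame_interval = 0.05),
    calibrate = list(grid = c(0.5, 2, 4, 8, 12), replicates = 2,
                     n_cells = 200))
}

validate_pipeline_config <- function(cfg) {
  need <- c("seed", "out_dir", "geometry", "stages")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("invalid pipeline config, missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!is.numeric(cfg$seed)) stop("seed must be numeric", call. = FALSE)
  g <- cfg$geometry
  if (is.null(g$length) || is.null(g$radius))
    stop("geometry needs length and radius", call. = FALSE)
  invisible(cfg)
}

#' Run the tracking-analysis pipeline end to end
#'
#' Executes the enabled stages (simulate -> [render -> localize] -> track ->
#' diffuse -> count -> spatial -> calibrate) with deterministic seeds, writing
#' every table as CSV and every fit as JSON into `out_dir`, plus a manifest
#' listing each artifact with its MD5 checksum, the stage timings, the seeds
#' used and the configuration hash.
#'
#' @param config A configuration list (see [default_pipeline_config()]) or
#'   the path of a YAML file holding one.
#' @param out_dir Optional override of `config$out_dir`.
#' @param seed Optional override of `config$seed`.
#' @param stages Optional character vector restricting which enabled stages
#'   run.
#' @param verbose Print stage progress (default TRUE).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL,
                         seed = NULL, stages = NULL, verbose = TRUE) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (!is.null(seed)) config$seed <- seed
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # frozen copy of the configuration; its hash marks every artifact
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  img <- do.call(imaging_config, config$imaging %||% list())
  trk <- do.call(tracking_config, config$tracking %||% list())
  geom <- cell_geometry(length = config$geometry$length,
                        radius = config$geometry$radius)
  ana <- config$analysis %||% list()
  thr <- ana$mobility_threshold %||% 1
  nst <- ana$n_steps %||% 4
  cutoff <- ana$periphery_cutoff %||% 0.5

  on_stage <- function(s) {
    isTRUE(config$stages[[s]]) && (is.null(stages) || s %in% stages)
  }
  manifest <- list(config_hash = cfg_hash, seed = config$seed,
                   stages = list(), files = list(), drop_counts = list())
  t_all <- proc.time()[3]
  say <- function(...) if (verbose) message(sprintf(...))
  artifacts <- character(0)

  loc <- NULL; tracks <- NULL; destim <- NULL

  if (on_stage("simulate")) {
    t0 <- proc.time()[3]
    sim <- config$simulate
    mix <- do.call(rbind, lapply(sim$species, function(s)
      c(D = s$D, weight = s$weight)))
    loc <- simulate_localized_tracks(
      geom, mix, mean_emitters_per_cell = sim$mean_per_cell %||% 1.5,
      n_cells = sim$n_cells %||% 120, n_frames = sim$n_frames %||% 10,
      config = img, seed = config$seed)
    f <- file.path(config$out_dir, "localizations.csv")
    utils::write.csv(loc, f, row.names = FALSE)
    artifacts <- c(artifacts, f)
    if (isTRUE(config$stages$render)) {
      paths <- list(simulate_trajectory(geom, sim$species[[1]]$D,
                                        sim$n_frames %||% 10, img,
                                        seed = config$seed + 1L))
      mv <- render_movie(paths, geom, img, seed = config$seed + 2L)
      fm <- file.path(config$out_dir, "demo_movie.tif")
      write_movie_tiff(mv, fm)
      artifacts <- c(artifacts, fm, paste0(fm, "_truth.csv"),
                     paste0(fm, "_config.json"))
      if (on_stage("localize")) {
        mloc <- localize_movie(mv, img)
        fl <- file.path(config$out_dir, "movie_localizations.csv")
        utils::write.csv(mloc, fl, row.names = FALSE)
        artifacts <- c(artifacts, fl)
      }
    }
    manifest$stages$simulate <- round(proc.time()[3] - t0, 3)
    say("simulate: %d localizations", nrow(loc))
  }

  if (on_stage("track")) {
    if (is.null(loc)) {
      f <- file.path(config$out_dir, "localizations.csv")
      if (!file.exists(f))
        stop("stage 'track': missing input ", f, call. = FALSE)
      loc <- utils::read.csv(f)
    }
    t0 <- proc.time()[3]
    tracks <- link(loc[, c("cell_id", "frame", "x_um", "y_um")], trk)
    f <- file.path(config$out_dir, "trajectories.csv")
    utils::write.csv(as.data.frame(tracks), f, row.names = FALSE)
    artifacts <- c(artifacts, f)
    manifest$stages$track <- round(proc.time()[3] - t0, 3)
    say("track: %d trajectories", length(unique(tracks$traj_id)))
  }

  if (on_stage("diffuse")) {
    if (is.null(tracks))
      stop("stage 'diffuse': run the track stage first", call. = FALSE)
    t0 <- proc.time()[3]
    destim <- apparent_D(tracks, n_steps = nst, dt = img$frame_interval,
                         mobility_threshold = thr)
    manifest$drop_counts$short_trajectories <-
      length(attr(destim, "excluded"))
    f <- file.path(config$out_dir, "apparent_D.csv")
    utils::write.csv(destim, f, row.names = FALSE)
    artifacts <- c(artifacts, f)
    rep <- list(config_hash = cfg_hash, n_trajectories = nrow(destim),
                fraction_slow = mean(destim$class == "slow"))
    if (nrow(destim) >= 50) {
      gm <- fit_gamma_mixture(destim$D_app, m = 2, constraints = c(0.5, NA))
      rep$gamma_mixture <- list(means = gm$means, weights = gm$weights,
                                constrained = gm$constrained,
                                logLik = gm$logLik, converged = gm$converged)
    }
    sq <- squared_displacements(tracks)
    if (length(sq) >= 200) {
      cf <- fit_cdf(sq, m = 2, s_axis = img$loc_error_axis,
                    dt = img$frame_interval)
      rep$cdf_fit <- list(D = cf$D, weights = cf$weights,
                          resid_norm = cf$resid_norm)
    }
    fj <- file.path(config$out_dir, "diffusion_report.json")
    jsonlite::write_json(rep, fj, auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, fj)
    manifest$stages$diffuse <- round(proc.time()[3] - t0, 3)
    say("diffuse: %d trajectories with D_app", nrow(destim))
  }

  if (on_stage("count")) {
    t0 <- proc.time()[3]
    cc <- config$count
    traces <- simulate_bleach_traces(
      n_cells = cc$n_cells %||% 60,
      molecules_per_cell = cc$molecules_per_cell %||% 3,
      unitary_intensity = cc$unitary_intensity %||% 8.7,
      bleach_rate = 1 / (cc$bleach_lifetime_s %||% 3.4),
      noise_sd = cc$noise_sd %||% 2.4,
      frame_interval = cc$frame_interval %||% 0.05,
      seed = config$seed + 10L)
    fits <- apply(traces$traces, 2, function(tr)
      hmm_steps(subtract_baseline(tr)))
    heights <- unlist(lapply(fits, `[[`, "step_heights"))
    uinfo <- if (length(heights) >= 30) unitary_intensity(heights) else NULL
    rep <- list(config_hash = cfg_hash,
                cells = lapply(seq_along(fits), function(i) list(
                  cell_id = i, n_steps = fits[[i]]$n_steps,
                  u = fits[[i]]$u,
                  molecules = fits[[i]]$states[1])),
                unitary_intensity = uinfo$u, unitary_sd = uinfo$sd,
                true_unitary = traces$unitary_intensity)
    fj <- file.path(config$out_dir, "counting_report.json")
    jsonlite::write_json(rep, fj, auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, fj)
    manifest$stages$count <- round(proc.time()[3] - t0, 3)
    say("count: %d traces fitted", length(fits))
  }

  if (on_stage("spatial")) {
    if (is.null(loc) || is.null(destim))
      stop("stage 'spatial': needs simulate and diffuse outputs", call. = FALSE)
    t0 <- proc.time()[3]
    # localizations are already in each cell's local frame
    norm <- normalize_position(loc[, c("x_um", "y_um")], geom)
    manifest$drop_counts$outside_outline <- attr(norm, "n_dropped")
    summ <- if (nrow(norm) >= 100)
      enrichment(norm, cutoff = cutoff, seed = config$seed + 20L) else NULL
    rep <- list(config_hash = cfg_hash, n_positions = nrow(norm),
                n_dropped = attr(norm, "n_dropped"))
    if (!is.null(summ))
      rep$enrichment <- list(periphery = summ$enrichment_periphery,
                             midcell = summ$enrichment_midcell,
                             ci_periphery = summ$ci_periphery,
                             ci_midcell = summ$ci_midcell)
    f <- file.path(config$out_dir, "unit_cell.csv")
    utils::write.csv(norm, f, row.names = FALSE)
    fj <- file.path(config$out_dir, "spatial_report.json")
    jsonlite::write_json(rep, fj, auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, f, fj)
    manifest$stages$spatial <- round(proc.time()[3] - t0, 3)
    say("spatial: %d unit-cell positions", nrow(norm))
  }

  if (on_stage("calibrate")) {
    t0 <- proc.time()[3]
    cb <- config$calibrate
    cal <- calibrate(cb$grid, geom, img,
                     n_cells = cb$n_cells %||% 200,
                     replicates = cb$replicates %||% 2,
                     tracking = trk, seed = config$seed + 30L)
    rep <- list(config_hash = cfg_hash, true_D = cal$true_D,
                apparent_mean = cal$apparent_mean,
                apparent_sd = cal$apparent_sd)
    fj <- file.path(config$out_dir, "calibration.json")
    jsonlite::write_json(rep, fj, auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, fj)
    manifest$stages$calibrate <- round(proc.time()[3] - t0, 3)
    say("calibrate: grid of %d", length(cb$grid))
  }

  manifest$files <- lapply(artifacts, function(f)
    list(path = basename(f), md5 = unname(tools::md5sum(f))))
  manifest$total_seconds <- round(proc.time()[3] - t_all, 3)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
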