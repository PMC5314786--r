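test_that("MSD reproduces noise-floor, ballistic and Brownian closed forms", {
  set.seed(51)
  # immobile emitter with per-axis error s: MSD = 4 s^2 at all lags
  tr <- data.frame(frame = 1:400,
                   x_um = rnorm(400, sd = 0.04), y_um = rnorm(400, sd = 0.04))
  m <- msd(tr, max_lag = 4, dt = 0.005)
  expect_true(all(abs(m$msd - 4 * 0.04^2) < 3 * m$se))
  # ballistic motion: MSD(t) = v^2 t^2 exactly
  v <- 3
  tr2 <- data.frame(frame = 1:50, x_um = v * (1:50) * 0.005, y_um = 0)
  m2 <- msd(tr2, max_lag = 5, dt = 0.005)
  expect_equal(m2$msd, v^2 * m2$lag_s^2, tolerance = 1e-12)
  # free 2D diffusion: slope of MSD vs lag = 4D
  steps <- matrix(rnorm(2 * 5000, sd = sqrt(2 * 2 * 0.005)), ncol = 2)
  tr3 <- data.frame(frame = 1:5001, x_um = cumsum(c(0, steps[, 1])),
                    y_um = cumsum(c(0, steps[, 2])))
  m3 <- msd(tr3, max_lag = 4, dt = 0.005)
  slope <- coef(lm(msd ~ 0 + lag_s, data = m3))[1]
  expect_lt(abs(slope / (4 * 2) - 1), 0.1)
  # truncation warning
  expect_warning(msd(tr2[1:3, ], max_lag = 10, dt = 0.005), "truncated")
})

test_that("apparent D matches hand arithmetic and excludes gap steps", {
  s <- sqrt(0.016)    # each squared step 0.016 um^2
  tr <- data.frame(traj_id = 1, frame = 1:5,
                   x_um = c(0, s, 0, s, 0), y_um = 0)
  d <- apparent_D(tr, n_steps = 4, dt = 0.005)
  expect_equal(d$D_app, 0.8, tolerance = 1e-12)
  # zero-length steps
  tr0 <- data.frame(traj_id = 1, frame = 1:5, x_um = 1, y_um = 2)
  expect_equal(apparent_D(tr0, dt = 0.005)$D_app, 0)
  # a gap step is excluded from sum and count: frames 1,2,3,4,6,7
  trg <- data.frame(traj_id = 1, frame = c(1:4, 6, 7),
                    x_um = c(0, s, 0, s, 5, 5 + s), y_um = 0)
  dg <- apparent_D(trg, n_steps = 4, dt = 0.005)
  expect_equal(dg$D_app, 0.8, tolerance = 1e-12)  # the 5-um jump never enters
  # too few single-frame steps -> excluded and reported
  tr_short <- data.frame(traj_id = 9, frame = c(1, 2, 4, 6, 8),
                         x_um = 0, y_um = 0)
  ds <- apparent_D(tr_short, dt = 0.005)
  expect_equal(nrow(ds), 0)
  expect_equal(attr(ds, "excluded"), "9")
})

test_that("fixed-cell pipeline gives mean apparent D near sigma^2/(4 dt)", {
  d <- fixed_cell_Dapp()
  expect_gt(nrow(d), 400)
  se <- sd(d$D_app) / sqrt(nrow(d))
  expect_lt(abs(mean(d$D_app) - 0.32), 3 * se + 0.01)
  # >= 90% of fixed-cell trajectories classified slow at 1 um^2/s
  expect_gte(mean(d$class == "slow"), 0.9)
  # consistency: inferred sigma equals 2s within 5%
  expect_lt(abs(precision_from_fixed(mean(d$D_app), 0.005)$sigma / 0.08 - 1),
            0.05)
})

test_that("precision relation evaluates exactly", {
  expect_identical(precision_from_fixed(0.32, 0.005)$sigma, 0.08)
  expect_equal(precision_from_fixed(0.32, 0.005)$s_axis, 0.04)
  expect_identical(precision_from_fixed(0, 0.005)$sigma, 0)
  expect_equal(precision_from_fixed(1.25, 0.005)$sigma, 0.1581,
               tolerance = 1e-4)
  expect_error(precision_from_fixed(-1, 0.005), ">= 0")
})

test_that("apparent D of a free species is gamma distributed (law check)", {
  g <- ecoli_cell()
  cfg0 <- strobe_config(loc_error_axis = 0)
  loc <- simulate_localized_tracks(g, cbind(2, 1), 1.5, n_cells = 3500,
                                   n_frames = 5, config = cfg0,
                                   substeps_per_frame = 1, seed = 52,
                                   unconfined = TRUE)
  loc$traj_id <- loc$emitter_id
  d <- apparent_D(loc, dt = 0.005)
  ks <- suppressWarnings(ks.test(d$D_app, pgamma, shape = 4, rate = 4 / 2))
  expect_gt(ks$p.value, 0.01)
  # with localization noise the mean shifts to D + s^2/dt
  cfg <- strobe_config()
  loc2 <- simulate_localized_tracks(g, cbind(8, 1), 1.5, n_cells = 3500,
                                    n_frames = 5, config = cfg,
                                    substeps_per_frame = 1, seed = 53,
                                    unconfined = TRUE)
  loc2$traj_id <- loc2$emitter_id
  d2 <- apparent_D(loc2, dt = 0.005)
  m <- 8 + 0.04^2 / 0.005
  ks2 <- suppressWarnings(ks.test(d2$D_app, pgamma, shape = 4, rate = 4 / m))
  expect_gt(ks2$p.value, 0.01)
})

test_that("gamma-mixture fitting recovers single and two-species data", {
  set.seed(54)
  x1 <- rgamma(2000, 4, rate = 4 / 2)
  f1 <- fit_gamma_mixture(x1, m = 1)
  expect_true(f1$converged)
  expect_lt(abs(f1$means - 2), 2 * 2 / sqrt(4 * 2000))
  # two-species fit of single-species data degenerates gracefully
  f2 <- fit_gamma_mixture(x1, m = 2)
  expect_gte(max(f2$weights), 0.9)
  expect_equal(sum(f2$weights), 1, tolerance = 1e-9)
  # constrained species report exactly their constraint
  set.seed(55)
  x3 <- c(rgamma(3800, 4, rate = 4 / 3.6), rgamma(200, 4, rate = 4 / 0.5))
  f3 <- fit_gamma_mixture(x3, m = 2, constraints = c(0.5, NA))
  expect_identical(f3$means[1], 0.5)
  expect_lt(abs(f3$means[2] - 3.6), 0.2)
  expect_lt(abs(f3$weights[2] - 0.95), 0.05)
  expect_error(fit_gamma_mixture(x1[1:30]), "at least 50")
})

test_that("mixture recovery holds in the median across seeds", {
  errs <- sapply(1:10, function(sd0) {
    set.seed(100 + sd0)
    x <- c(rgamma(3800, 4, rate = 4 / 3.6), rgamma(200, 4, rate = 4 / 0.5))
    f <- fit_gamma_mixture(x, m = 2, constraints = c(0.5, NA))
    c(abs(f$means[2] - 3.6), abs(f$weights[2] - 0.95) * 100)
  })
  expect_lt(median(errs[1, ]), 0.2)
  expect_lt(median(errs[2, ]), 5)
})

test_that("CDF fitting recovers two diffusive species (median over seeds)", {
  dt <- 0.005
  # noise-free displacements: both coefficients within 15%
  errs <- sapply(1:10, function(sd0) {
    set.seed(200 + sd0)
    u <- c(rexp(2000, 1 / (4 * 0.12 * dt)), rexp(8000, 1 / (4 * 7.6 * dt)))
    cf <- fit_cdf(u, m = 2, s_axis = 0, dt = dt)
    c(abs(cf$D[1] / 0.12 - 1), abs(cf$D[2] / 7.6 - 1), sum(cf$weights))
  })
  expect_lt(median(errs[1, ]), 0.15)
  expect_lt(median(errs[2, ]), 0.15)
  expect_equal(unname(errs[3, ]), rep(1, 10), tolerance = 1e-9)
  # with the 4 s^2 localization offset the fitted means (tau scale) stay
  # accurate; subtracting the offset amplifies the slow component's relative
  # error by tau/(tau - 4 s^2), which is the measurement's real geometry
  s <- 0.04
  tau <- 4 * c(0.12, 7.6) * dt + 4 * s^2
  terr <- sapply(1:10, function(sd0) {
    set.seed(200 + sd0)
    u <- c(rexp(2000, 1 / tau[1]), rexp(8000, 1 / tau[2]))
    cf <- fit_cdf(u, m = 2, s_axis = s, dt = dt)
    abs((4 * cf$D * dt + 4 * s^2) / tau - 1)
  })
  expect_lt(median(terr[1, ]), 0.10)
  expect_lt(median(terr[2, ]), 0.10)
})

test_that("CDF fit degenerates sensibly on single-species data", {
  set.seed(56)
  u <- rexp(5000, 1 / (4 * 2 * 0.005))
  cf <- fit_cdf(u, m = 2, s_axis = 0, dt = 0.005)
  expect_true(all(abs(cf$D - 2) < 0.2) || any(cf$weights < 0.05))
  cf0 <- fit_cdf(rep(1, 300), m = 2, s_axis = 0, dt = 0.005)
  expect_true(cf0$failed)
  expect_error(fit_cdf(u[1:100]), "at least 200")
})

test_that("cycle-budget arithmetic reproduces the diffusion-based cycle", {
  b <- cycle_budget()
  expect_identical(b$bound, 100000)
  expect_identical(b$searching, 275000)
  expect_equal(b$cycle_time, 0.400, tolerance = 1e-12)
  expect_equal(b$search_time, 0.300, tolerance = 1e-12)
  expect_equal(b$exploration_time, 0.0625, tolerance = 1e-12)
  expect_lte(b$exploration_time, 0.070)
  expect_equal(b$bound_fraction, 100000 / 375000)
  expect_error(cycle_budget(D = 0), "undefined")
  expect_error(cycle_budget(pool = 1000), "pool")
})

test_that("ideal-limit calibration returns the true coefficient", {
  # unconfined, no localization error, no blur: apparent = true
  g <- ecoli_cell()
  cfg0 <- strobe_config(loc_error_axis = 0)
  a <- rodSPT:::apparent_of_true(2, g, cfg0, n_cells = 400, mean_per_cell = 1.5,
                                 n_frames = 6, tracking = tracking_config(),
                                 substeps_per_frame = 1, seed = 57,
                                 unconfined = TRUE)
  expect_lt(abs(a - 2), 0.11)   # 3 SE of the gamma mean at ~900 trajectories
})

test_that("calibration is monotone and inverse-consistent on the grid", {
  g <- ecoli_cell()
  cal <- calibrate(c(1, 4, 8.1, 12), g, strobe_config(), n_cells = 150,
                   replicates = 2, seed = 58)
  expect_true(all(diff(cal$apparent_mean) > 0))
  for (i in seq_along(cal$true_D)) {
    inv <- predict(cal, cal$apparent_mean[i])
    expect_lt(abs(inv$accurate_D - cal$true_D[i]),
              max(3 * cal$apparent_sd[i], 0.3))
  }
  expect_error(predict(cal, 100), "range")
  expect_error(calibrate(c(4, 1), g), "increasing")
})
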