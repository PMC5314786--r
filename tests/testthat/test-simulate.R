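test_that("zero diffusion keeps the emitter at its start position", {
  g <- ecoli_cell()
  p <- simulate_trajectory(g, D = 0, n_frames = 20, seed = 1,
                           start = c(0.2, 0.1, -0.1))
  expect_true(all(p$frames[, 1] == 0.2))
  expect_true(all(p$substeps[, 3] == -0.1))
})

test_that("unconfined per-axis displacement variance matches 2*D*dt", {
  cfg <- strobe_config()
  p <- simulate_trajectory(NULL, D = 2, n_frames = 1e4, config = cfg,
                           substeps_per_frame = 1, seed = 3, unconfined = TRUE)
  v <- apply(p$substeps, 2, function(x) var(diff(x)))
  expected <- 2 * 2 * cfg$frame_interval           # 0.02 um^2
  se <- expected * sqrt(2 / (1e4 - 1))
  expect_true(all(abs(v - expected) < 3 * se))
})

test_that("confined positions satisfy the spherocylinder inequality exactly", {
  g <- ecoli_cell()
  p <- simulate_trajectory(g, D = 8, n_frames = 4000,
                           substeps_per_frame = 25, seed = 4)
  expect_true(all(inside_cell(p$substeps, g)))
  expect_true(all(inside_cell(p$frames, g)))   # strobe averages too (convexity)
})

test_that("long-time transverse variance approaches the uniform-disc value", {
  g <- ecoli_cell()     # r^2/4 = 0.0625 um^2 per axis in the cylindrical part
  p <- simulate_trajectory(g, D = 8, n_frames = 15000,
                           substeps_per_frame = 25, seed = 5)
  cyl <- abs(p$substeps[, 1]) <= 1
  expect_lt(abs(var(p$substeps[cyl, 2]) / 0.0625 - 1), 0.05)
  expect_lt(abs(var(p$substeps[cyl, 3]) / 0.0625 - 1), 0.05)
  # whole-cell variance is lower: hemispherical caps contribute r^2/5
  vol_cyl <- 2 * 1 * pi * 0.25; vol_cap <- 4 / 3 * pi * 0.125
  mix <- (vol_cyl * 0.0625 + vol_cap * 0.05) / (vol_cyl + vol_cap)
  expect_lt(abs(var(p$substeps[, 2]) / mix - 1), 0.05)
})

test_that("identical seed and config give bit-identical simulations", {
  g <- ecoli_cell()
  a <- simulate_trajectory(g, 3, 50, seed = 7)
  b <- simulate_trajectory(g, 3, 50, seed = 7)
  expect_identical(a$frames, b$frames)
  loc1 <- simulate_localized_tracks(g, cbind(2, 1), 1.5, 30, seed = 8)
  loc2 <- simulate_localized_tracks(g, cbind(2, 1), 1.5, 30, seed = 8)
  expect_identical(loc1, loc2)
})

test_that("localization tables carry the stated per-axis error", {
  g <- ecoli_cell()
  loc <- simulate_localized_tracks(g, cbind(0, 1), 1.5, n_cells = 200,
                                   n_frames = 8, seed = 9)
  err_x <- loc$x_um - loc$true_x_um
  expect_lt(abs(sd(err_x) - 0.04), 0.003)
  expect_lt(abs(mean(err_x)), 0.003)
})

test_that("Poisson emitter counts and exact noise-free identity hold", {
  g <- ecoli_cell()
  loc <- simulate_localized_tracks(g, cbind(1, 1), 1.5, n_cells = 500,
                                   n_frames = 2, seed = 10)
  n_emitters <- length(unique(loc$emitter_id))
  expect_lt(abs(n_emitters - 750), 3 * sqrt(750))
  cfg0 <- strobe_config(loc_error_axis = 0)
  loc0 <- simulate_localized_tracks(g, cbind(2, 1), 1.5, n_cells = 30,
                                    n_frames = 4, config = cfg0, seed = 11,
                                    unconfined = TRUE)
  expect_identical(loc0$x_um, loc0$true_x_um)
  expect_error(simulate_localized_tracks(g, cbind(numeric(0), numeric(0)),
                                         1.5, 10), "non-empty")
})

test_that("noiseless bleaching traces are quantized staircases", {
  tr <- simulate_bleach_traces(5, 3, unitary_intensity = 10,
                               bleach_rate = 1 / 2, noise_sd = 0, seed = 12)
  for (i in 1:5) {
    y <- tr$traces[, i]
    expect_equal(y[1], 30)
    expect_true(all(diff(y) <= 0))
    expect_true(all(y %in% c(0, 10, 20, 30)))
    expect_equal(y[length(y)], 0)   # 5 lifetimes out, everything bleached
  }
})

test_that("ensemble bleaching decay recovers the generator lifetime", {
  tr <- simulate_bleach_traces(1000, 3, 10, bleach_rate = 1 / 3.4,
                               noise_sd = 0.5, seed = 13)
  fit <- fit_lifetime(tr$time, rowMeans(tr$traces))
  expect_false(fit$failed)
  expect_lt(abs(fit$tau / 3.4 - 1), 0.1)
})

test_that("empty cells give pure-noise traces", {
  tr <- simulate_bleach_traces(50, 0, 10, 1 / 3, noise_sd = 2, seed = 14)
  expect_lt(abs(mean(tr$traces)), 0.1)
  expect_lt(abs(sd(as.vector(tr$traces)) - 2), 0.1)
})

test_that("uniform spatial pattern matches the disc-area oracle", {
  g <- ecoli_cell()
  sp <- sample_spatial_pattern(g, 1e5, "uniform", seed = 15)
  pts <- sp$points
  expect_true(all(inside_cell(pts, g)))
  cyl <- abs(pts[, 1]) <= 1
  rho <- sqrt(pts[cyl, 2]^2 + pts[cyl, 3]^2)
  frac <- mean(rho > 0.25)          # area ratio 1 - (1/2)^2 = 0.75
  se <- sqrt(0.75 * 0.25 / sum(cyl))
  expect_lt(abs(frac - 0.75), 3 * se)
})

test_that("bias = 0 periphery mode reduces to the uniform sampler", {
  g <- ecoli_cell()
  a <- sample_spatial_pattern(g, 4000, "periphery_biased", bias = 0, seed = 16)
  b <- sample_spatial_pattern(g, 4000, "uniform", seed = 17)
  rho_a <- sqrt(a$points[, 2]^2 + a$points[, 3]^2)
  rho_b <- sqrt(b$points[, 2]^2 + b$points[, 3]^2)
  expect_gt(suppressWarnings(ks.test(rho_a, rho_b)$p.value), 0.01)
  expect_error(sample_spatial_pattern(g, 10, "swirl"), "arg")
})
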