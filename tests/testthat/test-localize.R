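test_that("flat frames and infinite thresholds yield no candidates", {
  expect_equal(nrow(detect_candidates(matrix(7, 30, 30))), 0)
  fr <- gaussian_frame(30, 30, 14, 14, 1.4, 500, 5)
  expect_equal(nrow(detect_candidates(fr, intensity_threshold = Inf)), 0)
})

test_that("two well-separated spots are each detected within 1 px", {
  fr <- gaussian_frame(40, 40, 10, 20, 1.4, 800, 10) +
    gaussian_frame(40, 40, 20, 20, 1.4, 700, 0)
  cand <- detect_candidates(fr)
  expect_equal(nrow(cand), 2)
  got <- cand[order(cand$x_px), ]
  expect_lt(max(abs(got$x_px - c(10, 20))), 1.01)
  expect_lt(max(abs(got$y_px - c(20, 20))), 1.01)
})

test_that("close candidates are merged to the brighter one", {
  fr <- gaussian_frame(30, 30, 14, 14, 1.4, 800, 5)
  fr[14 + 1, 15 + 1] <- fr[14 + 1, 15 + 1] + 1  # a 1-px satellite maximum
  cand <- detect_candidates(fr)
  expect_equal(nrow(cand), 1)
})

test_that("elliptical Gaussian fit recovers a noiseless symmetric spot", {
  cfg <- strobe_config(em_gain = 1)
  px <- cfg$pixel_size
  fr <- gaussian_frame(25, 25, 12.30, 7.60, 1.4, 1000, 20)
  loc <- fit_spot(fr, c(12, 8), window_px = 11, config = cfg)
  expect_true(loc$fit_ok)
  expect_lt(abs(loc$x_um / px - 12.30), 1e-3)
  expect_lt(abs(loc$y_um / px - 7.60), 1e-3)
  expect_lt(abs(loc$wx_um / px - 1.4), 1e-3)
  expect_lt(abs(loc$wy_um / px - 1.4), 1e-3)
  expect_identical(loc$theta_rad, 0)   # canonicalized for symmetric spots
  # documented photon formula holds for the returned fields
  expect_equal(loc$photons,
               2 * pi * loc$amplitude * loc$wx_um * loc$wy_um /
                 (px^2 * cfg$em_gain))
})

test_that("degenerate windows are flagged instead of fitted", {
  cfg <- strobe_config()
  expect_false(fit_spot(matrix(5, 21, 21), c(10, 10), 9, cfg)$fit_ok)
  fr <- gaussian_frame(21, 21, 10, 10, 1.4)
  fr[3, 3] <- NaN
  expect_false(fit_spot(fr, c(10, 10), 17, cfg)$fit_ok)
  expect_error(fit_spot(fr, c(1, 1), 9, cfg), "window")
})

test_that("localization precision scales as photons^(-1/2) and is unbiased", {
  g <- ecoli_cell()
  levels <- c(150, 600, 2400)
  sds <- numeric(3); biases <- numeric(3)
  set.seed(31)
  for (li in seq_along(levels)) {
    cfg <- strobe_config(photons_per_strobe = levels[li], background_rate = 0.2,
                         em_gain = 10, read_noise = 2)
    p <- simulate_trajectory(g, 0, 1, cfg, start = c(0.153, 0.077, 0))
    errs <- matrix(NA_real_, 400, 2)
    for (r in 1:400) {
      mv <- render_movie(list(p), g, cfg, fov_px = c(21, 21),
                         origin_um = c(0.153, 0.077) - cfg$pixel_size * 10)
      loc <- fit_spot(mv$frames[[1]], c(10, 10), 11, cfg)
      if (loc$fit_ok)
        errs[r, ] <- c(loc$x_um - mv$truth$x_um[1], loc$y_um - mv$truth$y_um[1])
    }
    errs <- errs[stats::complete.cases(errs), ]
    sds[li] <- sqrt(mean(apply(errs, 2, var)))
    biases[li] <- max(abs(colMeans(errs)) / (apply(errs, 2, sd) / sqrt(nrow(errs))))
  }
  slope <- coef(lm(log(sds) ~ log(levels)))[2]
  expect_lt(abs(slope + 0.5), 0.05)
  expect_true(all(biases < 3))      # mean error within 3 SE of zero
})

test_that("rendering conserves photons and the centroid is unbiased", {
  g <- ecoli_cell()
  cfg <- strobe_config(photons_per_strobe = 1e4, background_rate = 0,
                       em_gain = 1, read_noise = 0)
  p <- simulate_trajectory(g, 0, 5, cfg, seed = 32, start = c(0.123, 0.071, 0))
  mv <- render_movie(list(p), g, cfg, seed = 33)
  sums <- vapply(mv$frames, sum, numeric(1))
  # Poisson with doubled (EMCCD excess) variance
  expect_true(all(abs(sums - 1e4) < 5 * sqrt(2 * 1e4)))
  fr <- mv$frames[[1]]
  cx <- sum((col(fr) - 1) * fr) / sum(fr)
  cy <- sum((row(fr) - 1) * fr) / sum(fr)
  expect_lt(abs(cx - mv$truth$x_um[1] / cfg$pixel_size), 0.05)
  expect_lt(abs(cy - mv$truth$y_um[1] / cfg$pixel_size), 0.05)
  # background-only movie: mean counts = gain * background
  cfg_bg <- strobe_config(background_rate = 3, em_gain = 5, read_noise = 2)
  mv0 <- render_movie(list(), g, cfg_bg, frame_count = 2, fov_px = c(40, 40),
                      origin_um = c(-2, -2), seed = 34)
  expect_lt(abs(mean(mv0$frames[[1]]) - 15), 0.5)
})

test_that("movie localization finds rendered emitters near their true spots", {
  g <- ecoli_cell()
  cfg <- strobe_config(photons_per_strobe = 3000, background_rate = 1,
                       em_gain = 10, read_noise = 5)
  p1 <- simulate_trajectory(g, 0, 2, cfg, seed = 35, start = c(-0.8, 0.2, 0))
  p2 <- simulate_trajectory(g, 0, 2, cfg, seed = 36, start = c(0.6, -0.3, 0))
  mv <- render_movie(list(p1, p2), g, cfg, seed = 37)
  loc <- localize_movie(mv, cfg)
  expect_equal(nrow(loc), 4)        # 2 emitters x 2 frames
  tr1 <- mv$truth[mv$truth$frame == 1, ]
  for (i in 1:2) {
    d <- sqrt((loc$x_um[loc$frame == 1] - tr1$x_um[i])^2 +
                (loc$y_um[loc$frame == 1] - tr1$y_um[i])^2)
    expect_lt(min(d), 0.02)
  }
})

test_that("TIFF round-trip preserves 16-bit counts", {
  g <- ecoli_cell()
  cfg <- strobe_config()
  p <- simulate_trajectory(g, 1, 3, cfg, seed = 38)
  mv <- render_movie(list(p), g, cfg, seed = 39)
  f <- tempfile(fileext = ".tif")
  write_movie_tiff(mv, f)
  back <- read_movie_tiff(f)
  expect_equal(length(back), 3)
  expect_equal(back[[2]], mv$frames[[2]], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(file.exists(paste0(f, "_truth.csv")))
})
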