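test_that("unit-cell normalization maps landmarks correctly", {
  g <- ecoli_cell()
  lm <- normalize_position(rbind(c(0, 0),        # cell center
                                 c(0, 0.5),      # lateral wall at mid-length
                                 c(1.5, 0),      # pole tip
                                 c(0.5, -0.25)), g)
  expect_equal(lm$x_norm, c(0, 0, 1, 1 / 3), tolerance = 1e-12)
  expect_equal(lm$y_norm, c(0, 1, 1, 0.5), tolerance = 1e-12)
  # a point well outside is dropped and counted
  out <- normalize_position(rbind(c(0, 0.9), c(0, 0)), g)
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_dropped"), 1)
  # rotated/translated cells use the local frame
  g2 <- cell_geometry(3, 0.5, center = c(5, 5), orientation = pi / 2)
  lm2 <- normalize_position(rbind(c(5, 6.5), c(4.5, 5)), g2)
  expect_equal(lm2$x_norm, c(1, 0), tolerance = 1e-12)
  expect_equal(lm2$y_norm, c(1, 1), tolerance = 1e-12)
})

test_that("the uniform-cylinder density is correct and normalized", {
  expect_equal(uniform_pdf(0), 4 / pi)
  expect_equal(uniform_pdf(1), 0)
  expect_lt(abs(integrate(uniform_pdf, 0, 1, rel.tol = 1e-10)$value - 1), 1e-6)
  expect_error(uniform_pdf(1.2), "rho")
  expect_error(uniform_pdf(-0.1), "rho")
})

test_that("uniform 3D samples follow the analytic short-axis law (KS)", {
  g <- ecoli_cell()
  sp <- sample_spatial_pattern(g, 2e4, "uniform", seed = 71)
  pts <- sp$points[abs(sp$points[, 1]) <= 1, ]   # cylindrical region
  y_norm <- abs(pts[, 2]) / 0.5
  ks <- suppressWarnings(ks.test(y_norm, uniform_cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("enrichment is null for uniform samples and exact for extremes", {
  g <- ecoli_cell()
  sp <- sample_spatial_pattern(g, 2e4, "uniform", seed = 72)
  pos <- normalize_position(sp$points[abs(sp$points[, 1]) <= 1, 1:2], g)
  e <- enrichment(pos, seed = 73)
  expect_lt(abs(e$enrichment_periphery), 5)
  expect_true(e$ci_periphery[1] <= 0 && e$ci_periphery[2] >= 0)
  # observed fractions always sum to one -> signed deviations oppose
  expect_equal(e$observed_periphery + e$observed_midcell, 1)
  expect_lt(e$enrichment_periphery * e$enrichment_midcell, 0)
  # all mass in the periphery: (1/0.3910 - 1)*100 ~ +155.7%
  all_per <- data.frame(y_norm = runif(500, 0.5, 1))
  ep <- enrichment(all_per, seed = 74)
  expect_equal(ep$uniform_periphery, 0.3910, tolerance = 1e-3)
  expect_equal(ep$enrichment_periphery,
               (1 / ep$uniform_periphery - 1) * 100, tolerance = 1e-9)
  expect_equal(ep$enrichment_periphery, 155.7, tolerance = 0.2)
})

test_that("periphery-biased patterns reproduce the quadrature oracle", {
  g <- ecoli_cell()
  bias <- 1.8
  # oracle: marginal short-axis mass above the cutoff under weight rho^bias
  chord <- function(y) sapply(y, function(yy)
    integrate(function(z) sqrt(yy^2 + z^2)^bias, 0, sqrt(1 - yy^2))$value)
  num <- integrate(chord, 0.5, 1)$value
  den <- integrate(chord, 0, 1)$value
  true_enr <- (num / den / rodSPT:::uniform_periphery_mass(0.5) - 1) * 100
  expect_equal(true_enr, 33, tolerance = 1.5)    # bias chosen near +33%
  sp <- sample_spatial_pattern(g, 3e4, "periphery_biased", bias = bias,
                               seed = 75)
  keep <- abs(sp$points[, 1]) <= 1
  pos <- data.frame(y_norm = abs(sp$points[keep, 2]) / 0.5)
  e <- enrichment(pos, seed = 76)
  expect_true(true_enr >= e$ci_periphery[1] && true_enr <= e$ci_periphery[2])
})

test_that("cell-length bins follow the printed edges", {
  pos <- data.frame(x_norm = runif(600), y_norm = runif(600)^0.5,
                    cell_len_um = rep(c(2.0, 3.0, 3.5), 200))
  b <- bin_by_length(pos)
  expect_equal(b$short$n, 200)
  expect_equal(b$long$n, 200)
  expect_equal(b$n_excluded, 200)                # 3.0 um falls between bins
  expect_true(all(is.na(b$bin[pos$cell_len_um == 3.0])))
  # uniform input: per-bin enrichments near zero
  g <- ecoli_cell()
  sp <- sample_spatial_pattern(g, 8000, "uniform", seed = 77)
  keep <- abs(sp$points[, 1]) <= 1
  posu <- normalize_position(sp$points[keep, 1:2], g)
  posu$cell_len_um <- rep(c(2, 4), length.out = nrow(posu))
  bu <- bin_by_length(posu)
  expect_lt(abs(bu$short$summary$enrichment_periphery), 8)
  expect_lt(abs(bu$long$summary$enrichment_periphery), 8)
})

test_that("slow/fast split recovers generator mixture fractions", {
  pos <- data.frame(traj_id = 1:500, y_norm = runif(500))
  dd <- data.frame(traj_id = 1:500, D_app = 0.2)
  sp <- slow_fast_split(pos, dd)
  expect_equal(sp$fraction_slow, 1)
  expect_equal(nrow(sp$fast), 0)
  # 88% fast / 12% slow at realistic operating points
  set.seed(78)
  n <- 4000
  is_slow <- runif(n) < 0.12
  D_app <- ifelse(is_slow, rgamma(n, 4, rate = 4 / 0.32),
                  rgamma(n, 4, rate = 4 / 8.3))
  pos2 <- data.frame(traj_id = 1:n, y_norm = runif(n))
  sp2 <- slow_fast_split(pos2, data.frame(traj_id = 1:n, D_app = D_app))
  expect_lt(abs(sp2$fraction_slow - 0.12), 0.03)
  expect_error(slow_fast_split(pos2, data.frame(traj_id = 1, D_app = 1)),
               "every position")
})
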