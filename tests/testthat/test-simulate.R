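test_that("identical configs give bit-identical regions", {
  cfg <- simulation_config(grid_rows = 10, grid_cols = 10, seed = 5)
  r1 <- suppressWarnings(simulate_region(cfg))
  r2 <- suppressWarnings(simulate_region(cfg))
  expect_identical(r1$area_table, r2$area_table)
  expect_identical(r1$graph$nb, r2$graph$nb)
})

test_that("with no mixing the deprivation field is the raw innovations (shifted)", {
  cfg <- simulation_config(grid_rows = 3, grid_cols = 3, autocorr_mix = 0,
                           smoothing_rounds = 0, noise_sd = 0.1,
                           n_segments = 3, seed = 1)
  reg <- simulate_region(cfg)
  set.seed(1)
  innov <- rnorm(9)
  # the nonnegativity affine map is a pure shift of the innovations
  expect_equal(reg$area_table$imd, innov - min(innov) + 0.5,
               tolerance = 1e-12)
})

test_that("neighbour-pair autocorrelation is non-decreasing in the mixing weight", {
  cors <- vapply(c(0, 0.4, 0.8), function(rho) {
    cfg <- simulation_config(grid_rows = 20, grid_cols = 20,
                             autocorr_mix = rho, smoothing_rounds = 5,
                             noise_sd = 0.2, seed = 7)
    reg <- suppressWarnings(simulate_region(cfg))
    oracle_neighbour_pair_cor(reg$area_table$imd, reg$graph)
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("invalid configuration fields are named in the error", {
  expect_error(simulation_config(grid_rows = 2, grid_cols = 2),
               "grid_rows")
  expect_error(simulation_config(autocorr_mix = 1), "autocorr_mix")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  expect_error(simulation_config(denominator_range = c(0, 10)),
               "denominator_range")
  expect_error(simulation_config(smoothing_rounds = -1),
               "smoothing_rounds")
})

test_that("null effects with tiny noise put every area near the baseline rate", {
  cfg <- simulation_config(grid_rows = 10, grid_cols = 10,
                           effect_target = 0, effect_differential = 0,
                           noise_sd = 1e-6,
                           denominator_range = c(2000L, 2000L), seed = 2)
  reg <- simulate_region(cfg)
  p0 <- 10^0.95 / 100
  # counts are binomial around denominator * p0
  expect_lt(max(abs(reg$area_table$notgood_count / 2000 - p0)), 0.03)
  expect_equal(mean(reg$area_table$notgood_count / 2000), p0,
               tolerance = 0.01)
})

test_that("moderate noise never hits the probability clipping bounds", {
  cfg <- simulation_config(grid_rows = 10, grid_cols = 10, noise_sd = 0.1,
                           effect_target = 0.1, effect_differential = 0.05,
                           seed = 4)
  reg <- simulate_region(cfg)
  comps <- reg$truth$components
  den <- stats::setNames(reg$area_table$denominator, reg$area_table$area_id)
  set.seed(99)
  cnt <- simulate_outcomes(comps, cfg, den)
  p <- cnt / den
  expect_true(all(p > 0 & p < 1))
})

test_that("an over-dispersed config is rejected rather than silently clipped", {
  cfg <- simulation_config(grid_rows = 5, grid_cols = 5, seed = 1)
  reg <- suppressWarnings(simulate_region(cfg))
  cfg_bad <- cfg
  cfg_bad$effect_target <- 1e308
  cfg_bad$baseline_log10_pct <- 1e308
  expect_error(simulate_outcomes(reg$truth$components, cfg_bad,
                                 stats::setNames(reg$area_table$denominator,
                                                 reg$area_table$area_id)),
               "not finite")
})

test_that("segments follow deprivation quantiles with bounded reassignment", {
  set.seed(31)
  dep <- stats::setNames(runif(2500, 0, 80), sprintf("a%04d", 1:2500))
  seg0 <- simulate_segments(dep, 13, seed = 3, reassign_frac = 0)
  expect_length(unique(seg0), 13)
  means <- tapply(dep, seg0, mean)
  expect_true(all(diff(means[sort(names(means))]) > 0))  # monotone in bin

  # with n_segments = 3 and no reassignment this is the tertile split
  seg3 <- simulate_segments(dep[1:900], 3, seed = 3, reassign_frac = 0)
  tert <- assign_tertiles(dep[1:900])
  expect_equal(unname(seg3 == "S03"),
               unname(tert == "Upper third (most deprived)"))

  # reassignment moves about 10% of areas by one adjacent bin
  seg1 <- simulate_segments(dep, 13, seed = 3, reassign_frac = 0.1)
  moved <- seg1 != seg0
  expect_lte(mean(moved), 0.1)
  expect_true(all(abs(as.integer(substr(seg1[moved], 2, 3)) -
                        as.integer(substr(seg0[moved], 2, 3))) == 1))

  expect_error(simulate_segments(dep, 2501), "exceeds")
  expect_error(simulate_segments(dep, 1), "at least 2")
})

test_that("closed-form standardized slopes follow the generator parameters", {
  cfg <- simulation_config()
  tot <- sqrt(0.6^2 + 0.3^2 + 0.74^2)
  expect_equal(unname(expected_std_slopes(cfg)),
               c(0.6, 0.3) / tot, tolerance = 1e-12)
})
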