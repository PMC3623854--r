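test_that("tertiles split ranked deprivation into equal thirds, ties stable", {
  lab <- assign_tertiles(stats::setNames(1:9, letters[1:9]))
  expect_setequal(names(lab)[lab == "Upper third (most deprived)"],
                  c("g", "h", "i"))
  expect_setequal(names(lab)[lab == "Medium third (middle deprived)"],
                  c("d", "e", "f"))
  expect_setequal(names(lab)[lab == "Lower third (least deprived)"],
                  c("a", "b", "c"))

  # n = 10: sizes 4/3/3, deterministic
  lab10 <- assign_tertiles(stats::setNames(10:1, letters[1:10]))
  expect_equal(as.integer(sort(table(lab10), decreasing = TRUE)),
               c(4L, 3L, 3L))
  expect_equal(unname(lab10["a"]), "Upper third (most deprived)")

  # all scores equal: assignment is by identifier order, deterministic
  labeq <- assign_tertiles(stats::setNames(rep(5, 6), c("f", "e", "d",
                                                        "c", "b", "a")))
  expect_equal(unname(labeq[c("a", "b")]),
               rep("Upper third (most deprived)", 2))
  expect_identical(labeq,
                   assign_tertiles(stats::setNames(rep(5, 6),
                                                   c("f", "e", "d", "c",
                                                     "b", "a"))))
  expect_error(assign_tertiles(c(1, 2)), "at least 3")
})

test_that("tertile sizes never differ by more than one", {
  set.seed(8)
  for (n in c(9, 10, 11, 47, 100)) {
    lab <- assign_tertiles(stats::setNames(rnorm(n), sprintf("a%03d", 1:n)))
    expect_lte(diff(range(table(lab))), 1)
  }
})

test_that("the beta ratio reproduces printed table rows and guards division", {
  expect_equal(round(beta_ratio(0.638, 0.688), 3), 0.927)
  expect_equal(round(beta_ratio(0.409, 0.055), 3), 7.436)
  expect_equal(round(beta_ratio(0.736, 0.237), 3), 3.105)
  expect_equal(beta_ratio(0.42, 0.42), 1)
  expect_error(beta_ratio(0.5, 0), "degenerate")
  expect_error(beta_ratio(0.5, 1e-12), "degenerate")
})

test_that("segment rows are ordered by descending ratio with name tie-breaks", {
  set.seed(12)
  n_seg <- 6
  ids <- sprintf("a%03d", 1:(n_seg * 60))
  pc1 <- rnorm(length(ids)); pc2 <- rnorm(length(ids))
  comps <- fake_components(ids, pc1, pc2)
  labels <- stats::setNames(rep(sprintf("seg%d", 1:n_seg), each = 60), ids)
  y <- 0.9 + 0.4 * pc1 + 0.2 * pc2 + rnorm(length(ids), sd = 0.3)
  tab <- data.frame(area_id = ids, outcome = "x", count = 1,
                    denominator = 10, percentage = 10, log10_pct = y)
  rep <- segment_regressions(tab, comps, labels)$x
  expect_equal(order(-rep$ratio, rep$segment), seq_len(nrow(rep)))
  expect_equal(rep$ratio, rep$beta1 / rep$beta2, tolerance = 1e-9)
  expect_true(all(rep$n_areas == 60))
})

test_that("segments are re-standardized internally: shifted copies give identical betas", {
  set.seed(13)
  n <- 80
  pc1 <- rnorm(n); pc2 <- rnorm(n)
  y <- 1 + 0.5 * pc1 + 0.2 * pc2 + rnorm(n, sd = 0.2)
  ids <- c(sprintf("a%03d", 1:n), sprintf("b%03d", 1:n))
  # segment B is segment A shifted by constants in every variable
  comps <- fake_components(ids, c(pc1, pc1 + 5), c(pc2, pc2 - 3))
  labels <- stats::setNames(rep(c("A", "B"), each = n), ids)
  tab <- data.frame(area_id = ids, outcome = "x", count = 1,
                    denominator = 10, percentage = 10,
                    log10_pct = c(y, y + 0.7))
  rep <- segment_regressions(tab, comps, labels)$x
  expect_equal(rep$beta1[rep$segment == "A"], rep$beta1[rep$segment == "B"],
               tolerance = 1e-10)
  expect_equal(rep$beta2[rep$segment == "A"], rep$beta2[rep$segment == "B"],
               tolerance = 1e-10)
})

test_that("undersized segments are dropped with a warning, not an error", {
  set.seed(14)
  ids <- sprintf("a%03d", 1:70)
  comps <- fake_components(ids, rnorm(70), rnorm(70))
  labels <- stats::setNames(c(rep("big", 60), rep("tiny", 10)), ids)
  tab <- data.frame(area_id = ids, outcome = "x", count = 1,
                    denominator = 10, percentage = 10,
                    log10_pct = rnorm(70, 1, 0.2))
  expect_warning(rep <- segment_regressions(tab, comps, labels)$x, "tiny")
  expect_equal(rep$segment, "big")
})

test_that("a null generator gives near-zero slopes within every tertile", {
  # under the null a standardized slope is a sample correlation with
  # SD ~ 1/sqrt(n_segment); tertiles of a 50x50 lattice (~833 areas)
  # put the 0.1 bound at ~3 SD
  cfg <- simulation_config(effect_target = 0, effect_differential = 0,
                           noise_sd = 0.15, seed = 17)
  reg <- simulate_region(cfg)
  out <- compute_outcomes(reg$area_table)
  comps <- reg$truth$components
  labels <- assign_tertiles(stats::setNames(reg$area_table$imd,
                                            reg$area_table$area_id))
  reps <- segment_regressions(out, comps, labels,
                              ranks = depdiff:::tertile_ranks(),
                              scheme = "imd_tertiles")
  for (rep in reps) {
    expect_gte(min(rep$n_areas), 800)
    expect_true(all(abs(rep$beta1) < 0.1))
    expect_true(all(abs(rep$beta2) < 0.1))
  }
})
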