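protocol <- labeling_protocol(chase_months = 12)

test_that("cohort simulation respects quiescence and the dilution law", {
  all_quiescent <- simulate_cohort(protocol,
                                   turnover_params("AL", 1, 5), 50, seed = 1)
  expect_true(all(all_quiescent$true_divisions == 0))
  expect_true(all(all_quiescent$true_excess == protocol$initial_excess))

  no_divisions <- simulate_cohort(protocol,
                                  turnover_params("AL", 0, 0), 50, seed = 2)
  expect_true(all(no_divisions$true_divisions == 0))

  # lambda*T = 2: CLT bound on the Poisson sample mean
  pp <- labeling_protocol(chase_months = 8)
  co <- simulate_cohort(pp, turnover_params("AL", 0, 0.25), 10000, seed = 3)
  expect_lt(abs(mean(co$true_divisions) - 2), 3 * sqrt(2 / 10000))

  # excess always equals the dilution law applied to the latent k
  expect_equal(co$true_excess,
               label_after_divisions(pp$initial_excess, co$true_divisions))

  # neurons are post-mitotic regardless of turnover parameters
  neurons <- simulate_cohort(protocol, turnover_params("HFD", 0, 3), 20,
                             cell_type = "neuron", seed = 4)
  expect_true(all(neurons$true_divisions == 0))
})

test_that("cohort simulation is deterministic under a fixed seed", {
  a <- simulate_cohort(protocol, default_turnover("CR"), 100, seed = 11)
  b <- simulate_cohort(protocol, default_turnover("CR"), 100, seed = 11)
  expect_identical(a, b)
})

test_that("invalid turnover parameters are rejected", {
  expect_error(turnover_params("AL", -0.1, 1), "p_quiescent")
  expect_error(turnover_params("AL", 0.5, -1), "division_rate")
  expect_error(labeling_protocol(natural_abundance = 0), "natural_abundance")
  expect_error(labeling_protocol(initial_excess = 1.1), "initial_excess")
})

test_that("MIMS synthesis matches Poisson expectations and ground truth", {
  # zero cells: empty masks, background-only counts
  cfg <- mims_sim_config(raster_dim = c(64, 64), n_frames = 1,
                         background_dose = 20, fiducials = 0)
  empty <- synthesize_mims_frames(protocol_cells <- data.frame(), cfg,
                                  seed = 5)
  expect_true(all(empty$masks == 0))
  expect_lt(mean(empty$frames[[1]]$channels$N14), 25)

  # determinism
  cells <- simulate_cohort(protocol, default_turnover("AL"), 4, seed = 6)
  cfg2 <- mims_sim_config(raster_dim = c(128, 128))
  s1 <- synthesize_mims_frames(cells, cfg2, seed = 7)
  s2 <- synthesize_mims_frames(cells, cfg2, seed = 7)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$masks, s2$masks)

  # expectation conservation before sampling: expected channel sums equal
  # dose x atom-fraction x hotspot integrals
  f <- cfg2$f_nat + ifelse(s1$masks > 0,
                           cells$true_excess[pmax(s1$masks, 1)], 0)
  dose <- ifelse(s1$masks > 0, cfg2$dose_per_px, cfg2$background_dose)
  hot <- s1$expected$N15 / (dose * f)  # recover hotspot field
  expect_equal(sum(s1$expected$N15), sum(dose * f * hot), tolerance = 1e-9)
  expect_equal(sum(s1$expected$N14), sum(dose * (1 - f) * hot),
               tolerance = 1e-9)
  expect_true(all(hot >= 1 - 1e-12))

  # per-pixel mean: e = 0.3, f_nat = 0.0037, D = 1000, no hotspot
  one <- data.frame(cell_id = "c1", cell_type = "beta", group = "AL",
                    true_divisions = 0, true_excess = 0.3)
  cfg3 <- mims_sim_config(raster_dim = c(200, 200), n_frames = 1,
                          dose_per_px = 1000, hotspot_fraction = 0,
                          radius_range = c(60, 60), fiducials = 0)
  sim <- synthesize_mims_frames(one, cfg3, seed = 8)
  px <- which(sim$masks == 1)
  expect_gte(length(px), 1e4)
  mean_expected <- 1000 * 0.3037
  se <- sqrt(mean_expected / length(px))
  expect_lt(abs(mean(sim$frames[[1]]$channels$N15[px]) - 303.7), 3 * se)
})

test_that("MIMS synthesis fails when nuclei cannot fit", {
  cells <- simulate_cohort(protocol, default_turnover("AL"), 50, seed = 9)
  cfg <- mims_sim_config(raster_dim = c(32, 32), radius_range = c(8, 10))
  expect_error(synthesize_mims_frames(cells, cfg, seed = 10), "raster too small")
})

test_that("GRN run synthesis hits the requested edge probabilities", {
  truth <- grn_truth(n_tfs = 8, n_targets = 40, n_edges = 50,
                     p_tf_target = 0, seed = 12)
  # p_true = 1, p_false = 0: every run equals the truth
  rs <- synthesize_grn_runs(truth, n_runs = 5, p_true = 1, p_false = 0,
                            seed = 13)
  for (run in rs$runs)
    expect_setequal(paste(run$tf, run$target),
                    paste(truth$true_edges$tf, truth$true_edges$target))

  # binomial SE bound on mean per-edge support at p_true = 0.9
  rs2 <- synthesize_grn_runs(truth, n_runs = 100, p_true = 0.9,
                             p_false = 0.001, seed = 14)
  key_true <- paste(truth$true_edges$tf, truth$true_edges$target)
  support <- rowMeans(sapply(rs2$runs, function(run)
    key_true %in% paste(run$tf, run$target)))
  expect_lt(abs(mean(support) - 0.9), 3 * sqrt(0.9 * 0.1 / 100))

  expect_error(synthesize_grn_runs(truth, 10, p_true = 0.5, p_false = 0.6),
               "p_false < p_true")
})

test_that("activity matrix synthesis produces the requested mixtures", {
  specs <- data.frame(name = c("allOFF", "allON", "half"),
                      on_fraction = c(0, 1, 0.5),
                      on_mean = 0.8, on_sd = 0.02,
                      off_mean = 0.1, off_sd = 0.02)
  am <- synthesize_activity_matrix(500, specs, seed = 15)
  expect_true(all(am$activity >= 0 & am$activity <= 1))
  expect_true(all(am$activity[, "allOFF"] < 0.5))
  expect_true(all(am$activity[, "allON"] > 0.5))
  expect_lt(abs(sum(am$truth[, "half"]) - 250), 3 * sqrt(500 * 0.25))

  bad <- data.frame(name = "x", on_fraction = 0.5, on_mean = 1.2,
                    on_sd = 0.1, off_mean = 0.1, off_sd = 0.1)
  expect_error(synthesize_activity_matrix(10, bad), "in \\[0, 1\\]")
})

test_that("ion image synthesis respects effect sizes", {
  region_a <- 1:500
  region_b <- 501:1000
  specs <- data.frame(mz = c(100.1, 200.2), log_effect = c(0, 10))
  ions <- synthesize_ion_images(region_a, region_b, specs,
                                raster_dim = c(40, 40), seed = 16)
  # huge effect: disjoint supports, AUC exactly 1
  expect_equal(ion_auc(ions[[2]]$intensity[region_a],
                       ions[[2]]$intensity[region_b]), 1.0)
  # determinism
  ions2 <- synthesize_ion_images(region_a, region_b, specs,
                                 raster_dim = c(40, 40), seed = 16)
  expect_identical(ions, ions2)
  expect_error(synthesize_ion_images(1:10, 5:20, specs), "disjoint")
})

test_that("null ions give AUC near 0.5 at the null sampling scale", {
  n <- 100
  aucs <- sapply(1:50, function(i) {
    ion <- synthesize_ion_images(1:n, (n + 1):(2 * n),
                                 data.frame(mz = 1, log_effect = 0),
                                 raster_dim = c(20, 20), seed = 100 + i)[[1]]
    ion_auc(ion$intensity[1:n], ion$intensity[(n + 1):(2 * n)])
  })
  null_se <- sqrt((2 * n + 1) / (12 * n * n))
  expect_lt(abs(mean(aucs) - 0.5), 3 * null_se / sqrt(50))
})

test_that("tolerance curve synthesis follows the exponential decay", {
  flat <- synthesize_tolerance_curve(0, 150, timepoints = c(0, 30, 60),
                                     noise_sd = 0)
  expect_true(all(flat$glucose_mgdl == 150))

  cv <- synthesize_tolerance_curve(0.02, 150, timepoints = c(0, 30, 60),
                                   noise_sd = 0)
  expect_equal(cv$glucose_mgdl[1], 150)
  expect_equal(cv$glucose_mgdl[3], 150 * exp(-1.2), tolerance = 1e-12)
  expect_equal(150 * exp(-1.2), 45.17913, tolerance = 1e-6)

  expect_error(synthesize_tolerance_curve(0.02, -5), "baseline")
})
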