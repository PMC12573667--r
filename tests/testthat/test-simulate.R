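test_that("colony point process has the analytic mean at zero dose", {
  dm <- uniform_dose_map(0, region = c(10, 10), spacing = 0.5)
  params <- list(nc0 = 2.77, alpha = 0.32, beta = 0.031, delta = 0)
  counts <- unlist(lapply(1:5, function(s) {
    col <- simulate_colonies(dm, params = params, seed = s)
    partition_and_aggregate(col, dm)$NC
  }))  # 500 quadrat draws
  se <- sqrt(2.77 / length(counts))
  expect_lt(abs(mean(counts) - 2.77), 3 * se)
})

test_that("colony intensity at 2 Gy matches the LQ model evaluation", {
  # NC0 2.77, alpha 0.32, beta 0.031 at uniform 2 Gy: 2.77 e^-0.764 = 1.290
  expected <- 2.77 * exp(-0.32 * 2 - 0.031 * 4)
  dm <- uniform_dose_map(2, region = c(40, 40), spacing = 0.5)
  params <- list(nc0 = 2.77, alpha = 0.32, beta = 0.031, delta = 0)
  counts <- unlist(lapply(1:3, function(s) {
    partition_and_aggregate(simulate_colonies(dm, params = params,
                                              seed = 100 + s), dm)$NC
  }))
  expect_equal(expected, 1.290, tolerance = 1e-3)
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected / length(counts)))
})

test_that("colony simulation is deterministic for a fixed seed", {
  spec <- grid_pattern_spec("striped")
  dm <- render_dose_map(make_pattern_mask(spec, region = c(15, 10),
                                          spacing = 0.5), 5, spec,
                        spacing = 0.5)
  dist <- distance_to_peak_rim(segment_peaks(dm))
  params <- list(nc0 = 2.5, alpha = 0.25, beta = 0.035, delta = -0.04)
  c1 <- simulate_colonies(dm, dist, params, seed = 7)
  c2 <- simulate_colonies(dm, dist, params, seed = 7)
  expect_identical(c1, c2)
  expect_error(simulate_colonies(dm, distance_map(matrix(0, 2, 2), 0.5),
                                 params), "co-registered")
})

test_that("expected counts never increase with uniform dose when delta is 0", {
  params <- list(nc0 = 2.5, alpha = 0.25, beta = 0.035, delta = 0)
  means <- vapply(c(0, 2, 5, 10), function(D) {
    dm <- uniform_dose_map(D, region = c(30, 30), spacing = 0.5)
    mean(partition_and_aggregate(simulate_colonies(dm, params = params,
                                                   seed = D + 1), dm)$NC)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("simulated quadrat counts are Poisson-dispersed", {
  tab <- synthetic_quadrat_table(n = 3000, seed = 5)
  ctrl <- tab$NC[tab$D == 0]
  res <- poisson_dispersion_test(ctrl)
  expect_gt(res$p, 0.001)
  expect_lt(abs(res$dispersion - 1), 0.15)
})

test_that("the default experiment design yields 40 flasks", {
  cfg <- experiment_config(region = c(16, 8), spacing = 0.5)
  sim <- simulate_experiment(cfg, seed = 2)
  expect_length(sim$flasks, 40)  # 3 patterns x 3 doses x 4 reps + 4 controls
  expect_equal(sum(sim$manifest$pattern == "control"), 4)
  ctrl <- sim$flasks[[which(sim$manifest$pattern == "control")[1]]]
  expect_true(all(ctrl$dose$values == 0))
  open <- sim$flasks[[which(sim$manifest$pattern == "open")[1]]]
  expect_true(all(open$dist$values == 0))

  cfg1 <- experiment_config(nominal_doses = 5, replicates = 1,
                            region = c(16, 8), spacing = 0.5)
  sim1 <- simulate_experiment(cfg1, seed = 2)
  expect_length(sim1$flasks, 3 + 4)
})

test_that("control flasks recover the seeding rate over the whole design", {
  cfg <- experiment_config(patterns = "open", nominal_doses = 5,
                           replicates = 1, controls = 4,
                           region = c(32, 32), spacing = 0.5,
                           params = list(nc0 = 2.448, alpha = 0.2539,
                                         beta = 0.0388, delta = 0))
  sim <- simulate_experiment(cfg, seed = 31)
  ctrl_idx <- which(sim$manifest$pattern == "control")
  counts <- unlist(lapply(sim$flasks[ctrl_idx], function(f) {
    partition_and_aggregate(f$colonies, f$dose)$NC
  }))
  se <- sqrt(2.448 / length(counts))
  expect_lt(abs(mean(counts) - 2.448), 3 * se)
})

test_that("study-scale quadrat simulation reproduces the design layout", {
  cfg <- experiment_config(region = c(16, 8), spacing = 0.5)
  tab <- simulate_study_quadrats(cfg, seed = 3)
  expect_equal(nrow(tab), 40 * 16 * 8)
  expect_setequal(unique(tab$pattern), c("open", "striped", "dotted", "control"))
  expect_true(all(tab$D[tab$pattern == "control"] == 0))
  expect_true(all(tab$d[tab$pattern == "open"] == 0))
  # identical geometry across replicates of a condition
  r1 <- tab[tab$flask_id == "striped_5Gy_r1", c("D", "d")]
  r2 <- tab[tab$flask_id == "striped_5Gy_r2", c("D", "d")]
  expect_equal(r1$D, r2$D)
  # exact relative dose scaling between nominal doses
  r10 <- tab[tab$flask_id == "striped_10Gy_r1", "D"]
  expect_equal(r10, 2 * r1$D, tolerance = 1e-12)
  tab2 <- simulate_study_quadrats(cfg, seed = 3)
  expect_identical(tab, tab2)
})
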