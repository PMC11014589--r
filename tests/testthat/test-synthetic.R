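test_that("the cohort generator is a pure function of its seed", {
  p <- population_params(n_observers = 8, seed = 101)
  a <- generate_population(p)
  b <- generate_population(p)
  expect_identical(a, b)
  c <- generate_population(population_params(n_observers = 8, seed = 102))
  expect_false(identical(a$truth$true_b, c$truth$true_b))
  # generation does not disturb the ambient RNG stream
  set.seed(50); before <- rnorm(1)
  set.seed(50); invisible(generate_population(p)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noise-free observers lie exactly on the conservation line", {
  pop <- generate_population(noise_free_params(n = 12))
  cohort <- build_cohort(compute_bouma_table(pop$thresholds), pop$areas)
  expect_equal(cohort$lambda, cohort$V4 / pop$params$c_true^2)
  fit <- fit_conservation(cohort, "V4", n_boot = 0)
  expect_equal(fit$k, 1 / pop$params$c_true^2)
  expect_equal(fit$r_squared, 1)
})

test_that("simulated thresholds encode the Bouma factor and session gain", {
  p0 <- noise_free_params()
  thr <- simulate_thresholds(0.31, p0, seed = 1)
  expect_equal(nrow(thr), 16L)
  expect_equal(sort(unique(thr$meridian)),
               sort(c("upper", "lower", "left", "right")))
  expect_equal(bouma_from_threshold(thr$spacing_threshold_deg,
                                    thr$eccentricity_deg),
               rep(0.31, 16))
  # a 10% lambda gain is a 1/sqrt(1.1) threshold shrink in session 2
  pg <- population_params(threshold_noise_log_sd = 0,
                          session2_lambda_gain = 1.10)
  tab <- compute_bouma_table(simulate_thresholds(0.31, pg, seed = 1))
  expect_equal(tab$lambda_session2 / tab$lambda_session1, 1.10)
})

test_that("measured Bouma factors are unbiased for the truth at defaults", {
  p <- population_params(n_observers = 300, seed = 77)
  pop <- generate_population(p)
  tab <- compute_bouma_table(pop$thresholds)
  ratio <- tab$b_combined / pop$truth$true_b
  # session-2 gain shifts the combined estimate down by g^(-1/4);
  # beyond that the pipeline is unbiased up to Monte-Carlo error
  expected <- p$session2_lambda_gain^(-1 / 4)
  expect_equal(exp(mean(log(ratio))), expected, tolerance = 0.01)
})

test_that("V1-V3 areas are independent of crowding by construction", {
  rs <- vapply(1:200, function(s) {
    pop <- generate_population(population_params(n_observers = 49, seed = s))
    cor(pop$truth$lambda_true, pop$truth$V1)
  }, numeric(1))
  expect_gt(mean(abs(rs) < 0.3), 0.95)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("QUEST runs are reproducible and track a step observer", {
  cfg <- quest_config(seed = 12, prior_mean = log10(1.5))
  a <- simulate_quest_run(1.1, cfg)
  b <- simulate_quest_run(1.1, cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$trials), 35L)
  # noiseless step observer: the staircase bisects to the threshold
  step_cfg <- quest_config(guess_rate = 0, lapse_rate = 0, slope = 1e6,
                           prior_mean = log10(1.2), seed = 3)
  est <- simulate_quest_run(1.0, step_cfg)
  expect_lt(abs(est$log10_threshold - log10(1.0)), 2 * step_cfg$grid_step)
  expect_error(
    simulate_quest_run(1, quest_config(grid_range = 0.001, grid_step = 1)),
    "degenerate"
  )
})

test_that("QUEST threshold estimates concentrate near the truth", {
  cfg <- quest_config(prior_mean = log10(1.5), seed = NULL)
  set.seed(91)
  est <- vapply(1:150, function(i) simulate_quest_run(1.1, cfg)$threshold,
                numeric(1))
  expect_lt(abs(median(est) - 1.1) / 1.1, 0.1)
})

test_that("quest-driven thresholds feed the pipeline end to end", {
  p <- population_params(n_observers = 4, seed = 19)
  pop <- generate_population(p, use_quest = TRUE)
  tab <- compute_bouma_table(pop$thresholds)
  expect_equal(nrow(tab), 4L)
  # staircase estimates stay in the right regime
  expect_equal(tab$b_combined, pop$truth$true_b, tolerance = 0.25)
})

test_that("noise-free replication recovers c exactly in every replicate", {
  rec <- recovery_experiment(noise_free_params(n = 10, seed = 5),
                             n_replicates = 3, n_boot = 50)
  v4 <- rec$replicates[rec$replicates$map == "V4", ]
  expect_equal(v4$c, rep(1.36, 3), tolerance = 1e-8)
  expect_true(all(v4$c_covered))
  expect_equal(rec$summary$c_bias[rec$summary$map == "V4"], 0,
               tolerance = 1e-8)
})
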