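test_that("through-origin slope and cortical distance on exact data", {
  fit <- fit_conservation(line_cohort(0.5), n_boot = 0)
  expect_equal(fit$k, 0.5)
  expect_equal(fit$c, sqrt(2))
  expect_equal(fit$r_squared, 1)
  # a single duplicated pair forces the ratio
  dup <- data.frame(observer = 1:4, lambda = rep(540, 4), V4 = rep(1000, 4))
  expect_equal(fit_conservation(dup, n_boot = 0)$k, 0.54)
  expect_error(fit_conservation(data.frame(lambda = 1, V4 = 1), n_boot = 0),
               "at least 2")
  expect_error(
    fit_conservation(data.frame(lambda = c(1, 2), V4 = c(0, 0)), n_boot = 0),
    "not all zero"
  )
})

test_that("normal-equation slope matches a brute-force grid search", {
  set.seed(13)
  for (i in 1:5) {
    n <- sample(5:30, 1)
    cohort <- data.frame(
      observer = 1:n,
      lambda = exp(rnorm(n, 5.7, 0.4)),
      V4 = exp(rnorm(n, 6.5, 0.4))
    )
    fit <- fit_conservation(cohort, n_boot = 0)
    grid <- seq(fit$k * 0.5, fit$k * 1.5, length.out = 20001)
    sse <- vapply(grid, function(k) sum((cohort$lambda - k * cohort$V4)^2),
                  numeric(1))
    expect_equal(fit$k, grid[which.min(sse)],
                 tolerance = (grid[2] - grid[1]) / fit$k)
  }
})

test_that("variance explained relative to the mean behaves as defined", {
  cohort <- line_cohort(0.5)
  expect_equal(variance_explained_origin(cohort$lambda, cohort$V4, 0.5), 1)
  # nearly constant lambda with varying area: origin line much worse
  # than the mean, so R^2 goes negative
  lambda <- c(500, 501, 499, 500)
  area <- c(400, 900, 1500, 2200)
  k <- sum(area * lambda) / sum(area^2)
  expect_lt(variance_explained_origin(lambda, area, k), 0)
  expect_error(variance_explained_origin(rep(5, 3), 1:3, 1), "zero variance")
  # definitional identity against independent arithmetic
  set.seed(3)
  l <- exp(rnorm(12, 5.7, 0.5)); a <- exp(rnorm(12, 6.5, 0.5))
  k <- sum(a * l) / sum(a^2)
  expect_equal(variance_explained_origin(l, a, k),
               1 - sum((l - k * a)^2) / sum((l - mean(l))^2))
})

test_that("cortical crowding distance is the inverse square root of k", {
  expect_equal(round(cortical_crowding_distance(0.54), 2), 1.36)
  expect_equal(cortical_crowding_distance(1), 1)
  expect_equal(cortical_crowding_distance(0.25), 2)
  expect_equal(area_per_letter(0.54), 1 / 0.54)
  expect_equal(cortical_crowding_distance(0.54)^2, area_per_letter(0.54))
  expect_error(cortical_crowding_distance(0), "positive")
  expect_error(cortical_crowding_distance(-1), "positive")
})

test_that("pearson association matches its definition and rejects degeneracy", {
  cohort <- line_cohort(0.4)
  expect_equal(pearson_association(cohort$lambda, cohort$V4), 1)
  expect_error(pearson_association(rep(3, 4), 1:4), "zero variance")
  expect_error(pearson_association(1:2, 2:3), "at least 3")
  set.seed(9)
  l <- rnorm(20); a <- 0.3 * l + rnorm(20)
  expect_equal(pearson_association(l, a),
               mean((l - mean(l)) * (a - mean(a))) * 20 / 19 / (sd(l) * sd(a)))
})

test_that("standardized covariance ellipses have eigen-structure axes", {
  # exactly uncorrelated triple -> circle
  circ <- covariance_ellipse(c(-1, 0, 1), c(0, 1, 0))
  expect_equal(circ$r, 0)
  expect_equal(circ$axes[1], circ$axes[2])
  # perfect correlation -> degenerate ellipse along the diagonal
  line <- covariance_ellipse(1:5, 2 * (1:5))
  expect_lt(line$axes[2], 1e-6)
  expect_equal(line$angle, pi / 4)
  # axes match the eigenvalues of the correlation matrix at any r
  set.seed(17)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40, sd = 0.8)
  e <- covariance_ellipse(x, y, n_sd = 2)
  ev <- eigen(matrix(c(1, e$r, e$r, 1), 2))$values
  expect_equal(e$axes, 2 * sqrt(ev))
  expect_error(covariance_ellipse(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("k and c transform correctly under rescaling of the data", {
  set.seed(23)
  cohort <- data.frame(observer = 1:15, lambda = exp(rnorm(15, 5.7, 0.3)),
                       V4 = exp(rnorm(15, 6.5, 0.3)))
  fit <- fit_conservation(cohort, n_boot = 0)
  t_scale <- 2.5
  lam_scaled <- cohort; lam_scaled$lambda <- cohort$lambda * t_scale
  fit_l <- fit_conservation(lam_scaled, n_boot = 0)
  expect_equal(fit_l$k, fit$k * t_scale)
  expect_equal(fit_l$c, fit$c * t_scale^(-0.5))
  area_scaled <- cohort; area_scaled$V4 <- cohort$V4 * t_scale
  expect_equal(fit_conservation(area_scaled, n_boot = 0)$k, fit$k / t_scale)
})

test_that("bootstrap intervals are deterministic and degenerate correctly", {
  same <- data.frame(observer = 1:6, lambda = rep(540, 6), V4 = rep(1000, 6))
  ci <- bootstrap_ci(same, "V4", "k", n_boot = 200, seed = 1)
  expect_equal(ci$lower, ci$upper)
  expect_equal(ci$lower, rep(0.54, 2))
  set.seed(33)
  cohort <- data.frame(observer = 1:25, lambda = exp(rnorm(25, 5.7, 0.3)),
                       V4 = exp(rnorm(25, 6.5, 0.3)))
  a <- bootstrap_ci(cohort, "V4", "c", n_boot = 2000, seed = 42)
  b <- bootstrap_ci(cohort, "V4", "c", n_boot = 2000, seed = 42)
  expect_identical(a, b)
  # different seeds agree up to Monte-Carlo error at large n_boot
  d <- bootstrap_ci(cohort, "V4", "c", n_boot = 10000, seed = 43)
  e <- bootstrap_ci(cohort, "V4", "c", n_boot = 10000, seed = 44)
  expect_equal(d$lower, e$lower, tolerance = 0.02)
  expect_equal(d$upper, e$upper, tolerance = 0.02)
})

test_that("map comparison flags the conserved map and rejects shuffles", {
  # with conservation built into V4 only and no measurement noise, V4
  # has maximal r and maximal variance explained by construction
  pop0 <- generate_population(noise_free_params(n = 30, seed = 6))
  cohort0 <- build_cohort(compute_bouma_table(pop0$thresholds), pop0$areas)
  tab0 <- map_comparison(cohort0, n_boot = 0)
  expect_equal(tab0$map[tab0$best], "V4")
  expect_equal(tab0$r_squared[tab0$best], 1)
  # at the default noise level the correlation still singles out V4,
  # and the best flag tracks the maximal variance explained
  pop <- generate_population(population_params(n_observers = 30, seed = 6))
  cohort <- build_cohort(compute_bouma_table(pop$thresholds), pop$areas)
  tab <- map_comparison(cohort, n_boot = 0)
  expect_equal(tab$r[tab$map == "V4"], max(tab$r))
  expect_equal(tab$map[tab$best], tab$map[which.max(tab$r_squared)])
  # destroying the pairing leaves nothing for the origin line to explain
  shuffled <- cohort
  set.seed(8)
  shuffled$lambda <- sample(shuffled$lambda)
  tab_s <- map_comparison(shuffled, n_boot = 0)
  expect_true(all(tab_s$r_squared < 0.2))
  # with two observers, the origin slope lies between the two ratios
  t2 <- fit_conservation(table2_cohort(), n_boot = 0)
  ratios <- table2_cohort()$lambda / table2_cohort()$V4
  expect_gt(t2$k, min(ratios))
  expect_lt(t2$k, max(ratios))
})

test_that("two-observer summary reproduces the worked ratios", {
  tab <- observer_pair_summary(table2_cohort())
  expect_equal(unlist(tab["Ratio", c("lambda", "V1", "V2", "V3", "V4")],
                      use.names = FALSE),
               c(2.5, 1.2, 1.0, 1.1, 2.4))
  ident <- table2_cohort()[c(1, 1), ]
  ident$observer <- c("A", "B")
  expect_true(all(observer_pair_summary(ident)["Ratio", ] == 1))
  expect_error(observer_pair_summary(table2_cohort()[1, ]), "exactly 2")
})

test_that("conservation_fit methods are coherent", {
  cohort <- table2_cohort()
  fit <- fit_conservation(cohort, "V4", n_boot = 300, seed = 2)
  expect_named(coef(fit), "k")
  expect_equal(predict(fit), fit$k * cohort$V4)
  expect_equal(predict(fit, data.frame(V4 = 1000)), fit$k * 1000)
  expect_equal(residuals(fit), cohort$lambda - fitted(fit))
  ci <- confint(fit, "c", level = 0.68)
  expect_true(ci[1, "lower"] <= fit$c && fit$c <= ci[1, "upper"])
  expect_output(print(fit), "letters/mm\\^2")
  expect_output(print(summary(fit)), "area per letter")
  pdf(NULL)
  on.exit(dev.off())
  big <- fit_conservation(line_cohort(0.5, areas = c(400, 700, 1000, 1600)),
                          n_boot = 0)
  expect_silent(plot(big))
})
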