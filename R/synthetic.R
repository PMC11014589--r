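#' Generative settings for a synthetic observer cohort
#'
#' Defines the population model used to emulate the statistical
#' structure the conservation analysis assumes: inter-observer Bouma
#' factors are lognormal; each observer's V4 surface area follows the
#' conservation relation \eqn{A_{V4} = \lambda c^2} up to lognormal
#' scatter, while V1-V3 areas are lognormal and statistically
#' independent of crowding; spacing thresholds carry multiplicative
#' per-location measurement noise, with a practice effect that
#' improves session-2 letter counts by a fixed gain.
#'
#' Defaults describe a realistic cohort: 49 observers; median Bouma
#' factor 0.27 with log-SD 0.17 (about a two-fold range across healthy
#' adults); 10% per-location threshold noise; a 10% session-2
#' improvement in \eqn{\lambda}; a true cortical crowding distance of
#' 1.36 mm; V4 area scatter (log-SD 0.37) calibrated so the cohort
#' correlation between \eqn{\lambda} and V4 area is about 0.65; V1-V3
#' median areas 2800, 2790 and 1980 mm^2 with log-SD 0.2.
#'
#' @param n_observers Cohort size (>= 2).  Default 49.
#' @param b_median Median true Bouma factor.  Default 0.27.
#' @param b_log_sd SD of log true Bouma factor.  Default 0.17.
#' @param threshold_noise_log_sd SD of the per-location, per-session
#'   multiplicative (log-domain) threshold measurement noise.
#'   Default 0.10.
#' @param session2_lambda_gain Multiplicative improvement of
#'   \eqn{\lambda} in session 2 (default 1.10).  Since \eqn{\lambda
#'   \propto b^{-2}}, session-2 thresholds are divided by the square
#'   root of this gain.
#' @param c_true True cortical crowding distance in mm linking V4 area
#'   to \eqn{\lambda} (default 1.36).
#' @param v4_area_log_noise_sd SD of the lognormal scatter of V4 area
#'   around \eqn{\lambda c^2}.  Default 0.37.
#' @param v123_area_medians Named vector of median V1-V3 bilateral
#'   areas in mm^2.
#' @param v123_area_log_sd SD of log V1-V3 areas.  Default 0.2.
#' @param seed Integer seed; the generator is a pure function of the
#'   parameters including this seed.
#' @return A list of class `"population_params"`.
#' @export
population_params <- function(n_observers = 49, b_median = 0.27,
                              b_log_sd = 0.17,
                              threshold_noise_log_sd = 0.10,
                              session2_lambda_gain = 1.10,
                              c_true = 1.36, v4_area_log_noise_sd = 0.37,
                              v123_area_medians = c(V1 = 2800, V2 = 2790,
                                                    V3 = 1980),
                              v123_area_log_sd = 0.2, seed = 1L) {
  check_scalar(n_observers, "n_observers", 1)
  check_scalar(b_median, "b_median", 0)
  check_scalar(b_log_sd, "b_log_sd", 0, strict = FALSE)
  check_scalar(threshold_noise_log_sd, "threshold_noise_log_sd", 0,
               strict = FALSE)
  check_scalar(session2_lambda_gain, "session2_lambda_gain", 0)
  check_scalar(c_true, "c_true", 0)
  check_scalar(v4_area_log_noise_sd, "v4_area_log_noise_sd", 0,
               strict = FALSE)
  check_scalar(v123_area_log_sd, "v123_area_log_sd", 0, strict = FALSE)
  if (length(v123_area_medians) != 3L || any(v123_area_medians <= 0)) {
    stop("'v123_area_medians' must be three positive areas (V1, V2, V3)")
  }
  names(v123_area_medians) <- c("V1", "V2", "V3")
  structure(
    list(n_observers = as.integer(n_observers), b_median = b_median,
         b_log_sd = b_log_sd,
         threshold_noise_log_sd = threshold_noise_log_sd,
         session2_lambda_gain = session2_lambda_gain, c_true = c_true,
         v4_area_log_noise_sd = v4_area_log_noise_sd,
         v123_area_medians = v123_area_medians,
         v123_area_log_sd = v123_area_log_sd, seed = as.integer(seed)),
    class = "population_params"
  )
}

#' Simulate the 16 spacing thresholds of one observer
#'
#' Generates one observer's crowding-threshold table (4 cardinal
#' meridians x 2 eccentricities x 2 sessions).  The noise route draws
#' each threshold from the observer's Bouma law with multiplicative
#' lognormal measurement noise,
#' \eqn{s = b\,\varphi\, e^{\eta}}, \eqn{\eta \sim N(0,
#' \sigma_{thr}^2)}; session-2 thresholds are additionally divided by
#' \eqn{\sqrt{g}} so that the session-2 letter count improves by the
#' gain \eqn{g}.  With `use_quest = TRUE` each threshold is instead
#' estimated by a full simulated QUEST staircase run against the
#' noise-free true threshold, so measurement error arises from the
#' staircase itself.
#'
#' @param true_b The observer's true Bouma factor.
#' @param params A [population_params()] object (noise and session
#'   gain are read from it).
#' @param observer Observer identifier for the output rows.
#' @param eccentricities Tested eccentricities in degrees.
#' @param use_quest Estimate each threshold with
#'   [simulate_quest_run()] instead of drawing lognormal noise.
#' @param quest A [quest_config()] used when `use_quest = TRUE`; its
#'   prior mean is re-centred per eccentricity on a nominal Bouma-law
#'   guess (b = 0.3).
#' @param seed Optional seed (the cohort generator seeds globally
#'   instead).
#' @return A 16-row thresholds data frame (columns `observer`,
#'   `meridian`, `eccentricity_deg`, `session`,
#'   `spacing_threshold_deg`).
#' @export
simulate_thresholds <- function(true_b, params = population_params(),
                                observer = "obs", eccentricities = c(5, 10),
                                use_quest = FALSE, quest = quest_config(),
                                seed = NULL) {
  check_scalar(true_b, "true_b", 0)
  grid <- expand.grid(
    session = 1:2, eccentricity_deg = eccentricities,
    meridian = MERIDIANS, stringsAsFactors = FALSE
  )
  with_seed(seed, {
    true_spacing <- true_b * grid$eccentricity_deg /
      ifelse(grid$session == 2, sqrt(params$session2_lambda_gain), 1)
    measured <- if (use_quest) {
      mapply(function(s, ecc) {
        cfg <- quest
        # experimenter's prior: nominal Bouma factor 0.3 at this
        # eccentricity, not the simulated observer's true threshold
        cfg$prior_mean <- log10(0.3 * ecc)
        simulate_quest_run(s, cfg, seed = NULL)$threshold
      }, true_spacing, grid$eccentricity_deg)
    } else {
      true_spacing * exp(stats::rnorm(nrow(grid), 0,
                                      params$threshold_noise_log_sd))
    }
    data.frame(
      observer = observer, meridian = grid$meridian,
      eccentricity_deg = grid$eccentricity_deg, session = grid$session,
      spacing_threshold_deg = measured
    )
  })
}

#' Generate a synthetic brain-and-behaviour cohort
#'
#' Draws a cohort of synthetic observers and everything the analysis
#' pipeline consumes: a per-observer ground-truth table, a raw
#' thresholds table (via [simulate_thresholds()]), and a long-format
#' areas table with left/right hemisphere rows.  True Bouma factors
#' are lognormal; V4 area is \eqn{\lambda(b)\,c^2 e^{\epsilon}} with
#' \eqn{\epsilon \sim N(0, \sigma_{V4}^2)}; V1-V3 areas are lognormal
#' and independent of crowding.  The generator is deterministic given
#' `params$seed`.
#'
#' @param params A [population_params()] object.
#' @param use_quest Simulate each threshold with a QUEST staircase run
#'   (slower); default FALSE uses the lognormal noise model.
#' @param quest A [quest_config()] for `use_quest = TRUE`.
#' @param phi0,a,phi_max Field constants used to map true Bouma
#'   factors to true letter counts.
#' @return A list of class `"synthetic_cohort"` with elements `truth`
#'   (observer, true_b, lambda_true, V1-V4 areas), `thresholds` (long
#'   thresholds table), `areas` (long per-hemisphere areas table), and
#'   `params`.
#' @examples
#' pop <- generate_population(population_params(n_observers = 6, seed = 2))
#' head(pop$truth)
#' @export
generate_population <- function(params = population_params(),
                                use_quest = FALSE, quest = quest_config(),
                                phi0 = 0.24, a = 2, phi_max = 10) {
  stopifnot(inherits(params, "population_params"))
  if (params$n_observers < 2L) stop("need at least 2 observers")
  n <- params$n_observers
  ids <- sprintf("S%03d", seq_len(n))
  with_seed(params$seed, {
    true_b <- exp(stats::rnorm(n, log(params$b_median), params$b_log_sd))
    lambda_true <- vapply(true_b, function(b) {
      uncrowded_letters(bouma_params(b, phi0 = phi0, a = a), phi_max)
    }, numeric(1))
    v4 <- lambda_true * params$c_true^2 *
      exp(stats::rnorm(n, 0, params$v4_area_log_noise_sd))
    v123 <- vapply(params$v123_area_medians, function(med) {
      exp(stats::rnorm(n, log(med), params$v123_area_log_sd))
    }, numeric(n))
    truth <- data.frame(
      observer = ids, true_b = true_b, lambda_true = lambda_true,
      V1 = v123[, "V1"], V2 = v123[, "V2"], V3 = v123[, "V3"], V4 = v4
    )
    thresholds <- do.call(rbind, lapply(seq_len(n), function(i) {
      simulate_thresholds(true_b[i], params, observer = ids[i],
                          use_quest = use_quest, quest = quest)
    }))
    areas <- do.call(rbind, lapply(VISUAL_MAPS, function(m) {
      # bilateral area split evenly between hemispheres for the
      # long-format file; the analysis only uses the L + R sum
      data.frame(
        observer = rep(ids, each = 2),
        map = m,
        hemisphere = rep(c("L", "R"), n),
        area_mm2 = rep(truth[[m]] / 2, each = 2)
      )
    }))
    structure(
      list(truth = truth, thresholds = thresholds, areas = areas,
           params = params),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d observers (seed %d)\n  median true b = %.3f, c_true = %.2f mm\n",
    x$params$n_observers, x$params$seed,
    stats::median(x$truth$true_b), x$params$c_true
  ))
  invisible(x)
}

#' Assemble the analysis cohort from behaviour and areas
#'
#' Merges a per-observer Bouma/\eqn{\lambda} table with a wide areas
#' table into the cohort data frame [fit_conservation()] consumes.
#'
#' @param bouma_table Output of [compute_bouma_table()].
#' @param areas Either the wide data frame returned by [read_areas()]
#'   (columns `observer`, `V1`..`V4`) or a long data frame with
#'   columns `observer`, `map`, `hemisphere`, `area_mm2` (summed
#'   across hemispheres first).
#' @return A data frame with columns `observer`, `lambda`, and one
#'   column per map.
#' @export
build_cohort <- function(bouma_table, areas) {
  if (all(c("map", "area_mm2") %in% names(areas))) {
    areas <- sum_hemispheres(areas)
  }
  miss_a <- setdiff(bouma_table$observer, areas$observer)
  miss_b <- setdiff(areas$observer, bouma_table$observer)
  if (length(miss_a) || length(miss_b)) {
    stop(sprintf(
      "observer sets differ between behaviour and areas (no areas: %s; no behaviour: %s)",
      paste(miss_a, collapse = ", "), paste(miss_b, collapse = ", ")
    ))
  }
  merge(bouma_table[, c("observer", "lambda")], areas, by = "observer")
}

#' Parameter-recovery experiment for the full pipeline
#'
#' Repeatedly generates a synthetic cohort, pushes it through the full
#' analysis (thresholds to Bouma factors to \eqn{\lambda}, then the
#' conservation fit for each map) and collects the recovered slope
#' \eqn{\hat k}, cortical crowding distance \eqn{\hat c}, correlation
#' \eqn{\hat r} and \eqn{\hat R^2} per map, plus whether the 68%
#' bootstrap CI for \eqn{c} in V4 covers the generative `c_true`.
#' Replicate seeds are derived deterministically from `params$seed`.
#'
#' @param params A [population_params()] object; `params$seed` anchors
#'   the replicate seed sequence.
#' @param n_replicates Number of replicate cohorts.
#' @param use_quest Simulate thresholds with QUEST staircases.
#' @param n_boot Bootstrap resamples per replicate for the V4 CI of c
#'   (0 skips CIs and coverage).
#' @param maps Maps to fit.
#' @return A list of class `"recovery_experiment"` with `replicates`
#'   (a long data frame: replicate, map, k, c, r, r_squared, and for
#'   V4 the c CI bounds and coverage flag) and `summary` (per-map
#'   means/SDs, mean r, coverage rate, and the bias of \eqn{\hat c}
#'   relative to `c_true`).
#' @examples
#' rec <- recovery_experiment(population_params(n_observers = 15),
#'                            n_replicates = 3, n_boot = 100)
#' rec$summary
#' @export
recovery_experiment <- function(params = population_params(),
                                n_replicates = 100, use_quest = FALSE,
                                n_boot = 1000, maps = VISUAL_MAPS) {
  check_scalar(n_replicates, "n_replicates", 0)
  rows <- vector("list", n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    p <- params
    p$seed <- (params$seed + 7919L * rep_i) %% .Machine$integer.max
    pop <- generate_population(p, use_quest = use_quest)
    tab <- compute_bouma_table(pop$thresholds)
    cohort <- build_cohort(tab, sum_hemispheres(pop$areas))
    fits <- lapply(maps, function(m) {
      boot <- if (m == "V4") n_boot else 0
      fit_conservation(cohort, m, n_boot = boot, conf_levels = 0.68,
                       seed = p$seed)
    })
    rows[[rep_i]] <- do.call(rbind, lapply(seq_along(maps), function(j) {
      f <- fits[[j]]
      ci <- if (!is.null(f$ci)) ci_lookup(f, "c", 0.68) else c(NA, NA)
      data.frame(
        replicate = rep_i, map = maps[j], k = f$k, c = f$c, r = f$r,
        r_squared = f$r_squared, c_ci_lo = ci[1], c_ci_hi = ci[2],
        c_covered = !is.na(ci[1]) && ci[1] <= params$c_true &&
          params$c_true <= ci[2]
      )
    }))
  }
  replicates <- do.call(rbind, rows)
  summary_df <- do.call(rbind, lapply(maps, function(m) {
    d <- replicates[replicates$map == m, ]
    data.frame(
      map = m,
      k_mean = mean(d$k), k_sd = stats::sd(d$k),
      c_mean = mean(d$c), c_sd = stats::sd(d$c),
      c_bias = mean(d$c) - params$c_true,
      r_mean = mean(d$r), r_squared_median = stats::median(d$r_squared),
      c_ci_coverage = if (m == "V4" && n_boot > 0) mean(d$c_covered)
                      else NA_real_
    )
  }))
  structure(
    list(replicates = replicates, summary = summary_df, params = params,
         n_replicates = n_replicates),
    class = "recovery_experiment"
  )
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replicate cohorts (n = %d, c_true = %.2f mm)\n",
              x$n_replicates, x$params$n_observers, x$params$c_true))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
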