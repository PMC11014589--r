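#' Fit the cortical-conservation model for one visual map
#'
#' Tests the conservation hypothesis that the number of letters fitting
#' in the uncrowded visual field is proportional to the surface area of
#' a retinotopic map: \eqn{\lambda = kA}, a linear model with the
#' intercept fixed at 0 and \eqn{A} as the independent variable.  The
#' least-squares slope is
#' \deqn{k = \frac{\sum_i A_i \lambda_i}{\sum_i A_i^2}}
#' in letters per mm^2, and the cortical crowding distance — the
#' center-to-center letter spacing on the cortical surface required at
#' threshold — is \eqn{c = k^{-1/2}} in mm.  Variance explained is
#' computed relative to the mean of \eqn{\lambda}
#' (\eqn{R^2 = 1 - \sum(\lambda_i - kA_i)^2 / \sum(\lambda_i -
#' \bar\lambda)^2}) and can be negative, because a line through the
#' origin may predict worse than the mean.  Uncertainty comes from a
#' percentile bootstrap over observers: whole observers (their
#' \eqn{\lambda} and area together) are resampled with replacement and
#' every statistic, including \eqn{k}, is refit within each resample.
#'
#' @param cohort A data frame with one row per observer holding a
#'   `lambda` column and one area column (mm^2, bilateral) per map, as
#'   produced by [build_cohort()].
#' @param map Name of the area column to fit against (default `"V4"`).
#' @param n_boot Number of bootstrap resamples (default 10000); set to
#'   0 to skip the bootstrap.
#' @param conf_levels Confidence levels for the percentile intervals
#'   (default 68% and 95%).
#' @param seed Integer seed making the resample sequence reproducible;
#'   `NULL` uses the ambient RNG.
#' @return An object of class `"conservation_fit"`: a list with
#'   elements `map`, `n`, `k`, `c`, `r`, `r_squared`, `ellipse` (the
#'   1-SD [covariance_ellipse()]), `ci` (a data frame of percentile
#'   bounds per statistic and level), `n_boot`, `boot_dropped` (count
#'   of degenerate resamples), `seed`, and `data`.
#' @seealso [map_comparison()] to fit all maps at once;
#'   [cortical_crowding_distance()]; [bootstrap_ci()].
#' @examples
#' cohort <- data.frame(observer = c("O1", "O2"), lambda = c(748, 302),
#'                      V4 = c(1483, 618))
#' fit <- fit_conservation(cohort, "V4", n_boot = 0)
#' coef(fit)
#' @export
fit_conservation <- function(cohort, map = "V4", n_boot = 10000,
                             conf_levels = c(0.68, 0.95), seed = NULL) {
  dat <- extract_map(cohort, map)
  fit <- origin_fit_stats(dat$lambda, dat$area)
  ell <- if (nrow(dat) >= 3L && stats::sd(dat$lambda) > 0 &&
             stats::sd(dat$area) > 0) {
    covariance_ellipse(dat$area, dat$lambda, n_sd = 1)
  } else {
    NULL
  }
  boot <- NULL
  if (n_boot > 0) {
    boot <- bootstrap_engine(dat$lambda, dat$area, n_boot = n_boot,
                             conf_levels = conf_levels, seed = seed)
  }
  structure(
    list(
      map = map, n = nrow(dat),
      k = fit$k, c = fit$c, r = fit$r, r_squared = fit$r_squared,
      ellipse = ell,
      ci = boot$ci, n_boot = if (is.null(boot)) 0L else n_boot,
      boot_dropped = boot$dropped, seed = seed,
      data = dat
    ),
    class = "conservation_fit"
  )
}

# pull (lambda, area) pairs for one map out of a cohort data frame
extract_map <- function(cohort, map) {
  if (!is.data.frame(cohort)) stop("'cohort' must be a data frame")
  if (!"lambda" %in% names(cohort)) stop("'cohort' must have a 'lambda' column")
  if (!map %in% names(cohort)) {
    stop(sprintf("no area column '%s' in the cohort", map))
  }
  dat <- data.frame(
    observer = if ("observer" %in% names(cohort)) cohort$observer
               else seq_len(nrow(cohort)),
    lambda = cohort$lambda, area = cohort[[map]]
  )
  if (nrow(dat) < 2L) stop("the conservation fit needs at least 2 observers")
  if (any(!is.finite(dat$lambda)) || any(dat$lambda <= 0)) {
    stop("'lambda' must be finite and positive for every observer")
  }
  if (any(!is.finite(dat$area)) || any(dat$area < 0) || all(dat$area == 0)) {
    stop("map areas must be finite, non-negative, and not all zero")
  }
  dat
}

# core statistics for one (lambda, area) sample; NA where undefined
origin_fit_stats <- function(lambda, area) {
  k <- sum(area * lambda) / sum(area^2)
  ss_tot <- sum((lambda - mean(lambda))^2)
  r2 <- if (ss_tot > 0) 1 - sum((lambda - k * area)^2) / ss_tot else NA_real_
  r <- if (length(lambda) >= 3L && stats::sd(lambda) > 0 &&
           stats::sd(area) > 0) {
    stats::cor(lambda, area)
  } else {
    NA_real_
  }
  list(k = k, c = if (k > 0) k^(-0.5) else NA_real_, r = r, r_squared = r2)
}

#' Cortical crowding distance from a conservation slope
#'
#' Converts the conservation slope `k` (letters per mm^2) into the
#' cortical crowding distance \eqn{c = k^{-1/2}} in mm — the
#' threshold center-to-center letter spacing on the cortical map.  The
#' reciprocal `1/k` is the cortical area claimed per letter
#' (mm^2/letter), i.e. \eqn{c^2}.
#'
#' @param k Conservation slope(s) in letters per mm^2, > 0.
#' @return Cortical crowding distance(s) in mm.
#' @examples
#' cortical_crowding_distance(0.54)  # 1.36 mm
#' area_per_letter(0.54)             # 1.85 mm^2
#' @export
cortical_crowding_distance <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("'k' must be finite and positive (letters per mm^2)")
  }
  k^(-0.5)
}

#' @rdname cortical_crowding_distance
#' @export
area_per_letter <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("'k' must be finite and positive (letters per mm^2)")
  }
  1 / k
}

#' Variance explained by the through-origin conservation line
#'
#' \eqn{R^2 = 1 - \sum(\lambda_i - kA_i)^2 / \sum(\lambda_i -
#' \bar\lambda)^2}.  Unlike ordinary regression this is not bounded
#' below by 0: a line through the origin can have larger residuals
#' than the horizontal line at the mean.
#'
#' @param lambda Per-observer letter counts.
#' @param area Per-observer map areas (mm^2).
#' @param k The fitted conservation slope.
#' @return The variance explained (<= 1, possibly negative).
#' @export
variance_explained_origin <- function(lambda, area, k) {
  stopifnot(length(lambda) == length(area))
  ss_tot <- sum((lambda - mean(lambda))^2)
  if (ss_tot == 0) stop("'lambda' has zero variance; R^2 undefined")
  1 - sum((lambda - k * area)^2) / ss_tot
}

#' Pearson correlation between letter count and map area
#'
#' Product-moment correlation treating the two variables
#' symmetrically, as a model-free complement to the conservation fit.
#'
#' @inheritParams variance_explained_origin
#' @return Pearson's r.
#' @export
pearson_association <- function(lambda, area) {
  stopifnot(length(lambda) == length(area))
  if (length(lambda) < 3L) stop("Pearson's r needs at least 3 observers")
  if (stats::sd(lambda) == 0 || stats::sd(area) == 0) {
    stop("Pearson's r undefined: a variable has zero variance")
  }
  stats::cor(lambda, area)
}

#' Standardized covariance ellipse of two variables
#'
#' Summarises the joint scatter of map area and letter count as an
#' ellipse in standardized coordinates: each variable is divided by
#' its standard deviation, so the covariance matrix becomes the
#' correlation matrix \eqn{[[1, r], [r, 1]]} with eigenvalues
#' \eqn{1 \pm r}.  Ellipse semi-axes are `n_sd` times the square roots
#' of the eigenvalues: a circle when r = 0, degenerating to the
#' diagonal when |r| = 1.  The major axis lies along the identity
#' diagonal for r > 0 and the anti-diagonal for r < 0.
#'
#' @param x,y Numeric vectors of equal length (at least 3 points).
#' @param n_sd Contour level in standard deviations (1 or 2 for the
#'   usual 1-SD / 2-SD contours).
#' @return A list with `center` (means of `x` and `y`), `sd`
#'   (standard deviations used for scaling), `r`, `axes` (semi-axis
#'   lengths in standardized units, major first), `angle` (major-axis
#'   angle in radians in standardized coordinates), and `n_sd`.
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- 0.6 * x + rnorm(50, sd = 0.8)
#' covariance_ellipse(x, y)$axes
#' @export
covariance_ellipse <- function(x, y, n_sd = 1) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("covariance ellipse needs at least 3 points")
  check_scalar(n_sd, "n_sd", 0)
  sdx <- stats::sd(x)
  sdy <- stats::sd(y)
  if (sdx == 0 || sdy == 0) {
    stop("covariance ellipse undefined: a variable has zero variance")
  }
  r <- stats::cor(x, y)
  # eigenvalues of [[1, r], [r, 1]] are 1 + |r| (along +-diagonal) and 1 - |r|
  axes <- n_sd * sqrt(c(1 + abs(r), 1 - abs(r)))
  list(
    center = c(mean(x), mean(y)), sd = c(sdx, sdy), r = r,
    axes = axes, angle = if (r >= 0) pi / 4 else -pi / 4, n_sd = n_sd
  )
}

# Vectorised percentile bootstrap over observers.  Resamples whole
# observers (lambda and area jointly), refits every statistic in each
# resample, and drops resamples with degenerate variance.
bootstrap_engine <- function(lambda, area, n_boot, conf_levels = c(0.68, 0.95),
                             seed = NULL) {
  n <- length(lambda)
  idx <- with_seed(seed, matrix(
    sample.int(n, n * n_boot, replace = TRUE), nrow = n
  ))
  L <- matrix(lambda[idx], nrow = n)
  A <- matrix(area[idx], nrow = n)

  k <- colSums(A * L) / colSums(A^2)
  c_val <- ifelse(k > 0, k^(-0.5), NA_real_)

  Lbar <- colMeans(L)
  ss_tot <- colSums((L - rep(Lbar, each = n))^2)
  ss_res <- colSums((L - rep(k, each = n) * A)^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)

  Abar <- colMeans(A)
  sxy <- colSums((L - rep(Lbar, each = n)) * (A - rep(Abar, each = n)))
  sxx <- colSums((A - rep(Abar, each = n))^2)
  r <- ifelse(ss_tot > 0 & sxx > 0, sxy / sqrt(ss_tot * sxx), NA_real_)

  stats_mat <- rbind(k = k, c = c_val, r = r, r_squared = r2)
  dropped <- sum(apply(is.na(stats_mat), 2, any))

  ci <- do.call(rbind, lapply(rownames(stats_mat), function(s) {
    do.call(rbind, lapply(conf_levels, function(lv) {
      q <- stats::quantile(stats_mat[s, ], probs = c((1 - lv) / 2, (1 + lv) / 2),
                           na.rm = TRUE, names = FALSE)
      data.frame(statistic = s, level = lv, lower = q[1], upper = q[2])
    }))
  }))
  rownames(ci) <- NULL
  list(ci = ci, dropped = dropped, samples = stats_mat)
}

#' Bootstrap confidence interval for a conservation statistic
#'
#' Percentile bootstrap over observers for any of the per-map
#' statistics: the conservation slope `k`, the cortical crowding
#' distance `c`, Pearson's `r`, or the through-origin `r_squared`.
#' Observers are resampled with replacement as whole units (their
#' letter count and area stay paired) and the statistic is recomputed
#' — including refitting `k` — within each resample.  Resamples where
#' a statistic is undefined (e.g. zero variance) are dropped and
#' counted.
#'
#' @inheritParams fit_conservation
#' @param statistic One of `"k"`, `"c"`, `"r"`, `"r_squared"`.
#' @return A data frame with one row per confidence level: columns
#'   `statistic`, `level`, `lower`, `upper`; attribute `"dropped"`
#'   counts degenerate resamples.
#' @examples
#' pop <- generate_population(population_params(n_observers = 20))
#' cohort <- build_cohort(compute_bouma_table(pop$thresholds), pop$areas)
#' bootstrap_ci(cohort, "V4", "c", n_boot = 500, seed = 7)
#' @export
bootstrap_ci <- function(cohort, map = "V4",
                         statistic = c("k", "c", "r", "r_squared"),
                         n_boot = 10000, conf_levels = c(0.68, 0.95),
                         seed = NULL) {
  statistic <- match.arg(statistic)
  dat <- extract_map(cohort, map)
  boot <- bootstrap_engine(dat$lambda, dat$area, n_boot = n_boot,
                           conf_levels = conf_levels, seed = seed)
  out <- boot$ci[boot$ci$statistic == statistic, ]
  rownames(out) <- NULL
  attr(out, "dropped") <- boot$dropped
  out
}

#' Compare conservation across visual maps
#'
#' Fits the conservation model to each retinotopic map and collects
#' slope, cortical crowding distance, correlation, variance explained,
#' and bootstrap intervals into one table.  The map with maximal
#' variance explained is flagged — under the conservation hypothesis
#' for a single map, that map should stand out.
#'
#' @inheritParams fit_conservation
#' @param maps Character vector of area column names (default V1-V4).
#' @return A data frame with one row per map: `map`, `n`, `k`, `c`,
#'   `r`, `r_squared`, CI columns for each statistic at 68% and 95%,
#'   and logical `best` marking the maximal `r_squared`.
#' @examples
#' pop <- generate_population(population_params(n_observers = 20))
#' cohort <- build_cohort(compute_bouma_table(pop$thresholds), pop$areas)
#' map_comparison(cohort, n_boot = 200, seed = 1)
#' @export
map_comparison <- function(cohort, maps = VISUAL_MAPS, n_boot = 10000,
                           conf_levels = c(0.68, 0.95), seed = NULL) {
  rows <- lapply(maps, function(m) {
    fit <- fit_conservation(cohort, m, n_boot = n_boot,
                            conf_levels = conf_levels, seed = seed)
    row <- data.frame(
      map = m, n = fit$n, k = fit$k, c = fit$c, r = fit$r,
      r_squared = fit$r_squared
    )
    if (!is.null(fit$ci)) {
      for (i in seq_len(nrow(fit$ci))) {
        ci <- fit$ci[i, ]
        tag <- sprintf("%s_%d", ci$statistic, round(ci$level * 100))
        row[[paste0(tag, "_lo")]] <- ci$lower
        row[[paste0(tag, "_hi")]] <- ci$upper
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  out$best <- out$r_squared == max(out$r_squared)
  rownames(out) <- NULL
  out
}

#' Side-by-side summary of two observers
#'
#' Tabulates the letter count and per-map surface areas of two
#' observers together with their first/second ratios (rounded to one
#' decimal), the format used to contrast a low-crowding against a
#' high-crowding observer.
#'
#' @param cohort A cohort data frame with exactly two rows.
#' @param maps Area columns to include.
#' @return A data frame with rows for each observer and a `Ratio` row;
#'   columns `lambda` and one per map.
#' @examples
#' cohort <- data.frame(observer = c("O1", "O2"), lambda = c(748, 302),
#'                      V1 = c(3052, 2580), V2 = c(2767, 2815),
#'                      V3 = c(2053, 1907), V4 = c(1483, 618))
#' observer_pair_summary(cohort)
#' @export
observer_pair_summary <- function(cohort, maps = VISUAL_MAPS) {
  if (nrow(cohort) != 2L) stop("observer_pair_summary needs exactly 2 observers")
  maps <- maps[maps %in% names(cohort)]
  vals <- as.matrix(cohort[, c("lambda", maps)])
  ratio <- round(vals[1, ] / vals[2, ], 1)
  out <- as.data.frame(rbind(vals, Ratio = ratio))
  rownames(out) <- c(as.character(cohort$observer), "Ratio")
  out
}
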