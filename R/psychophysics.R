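#' Convert a spacing threshold to a Bouma factor
#'
#' Divides the measured center-to-center spacing threshold by the
#' target eccentricity.  The eccentricity offset `phi0` is deliberately
#' omitted from this conversion: at the eccentricities where crowding
#' is measured (a few degrees and beyond) the 0.24 deg offset is
#' negligible relative to the eccentricity, while the letter-count
#' computation retains it.
#'
#' @param spacing_threshold Spacing threshold(s) in degrees, > 0.
#' @param eccentricity Target eccentricity in degrees, > 0 (recycled
#'   against `spacing_threshold`).
#' @return Unitless Bouma factor(s).
#' @examples
#' bouma_from_threshold(1.1, 5)   # 0.22
#' bouma_from_threshold(3.4, 10)  # 0.34
#' @export
bouma_from_threshold <- function(spacing_threshold, eccentricity) {
  if (any(!is.finite(spacing_threshold)) || any(spacing_threshold <= 0)) {
    stop("'spacing_threshold' must be finite and positive (degrees)")
  }
  if (any(!is.finite(eccentricity)) || any(eccentricity <= 0)) {
    stop("'eccentricity' must be finite and positive (degrees)")
  }
  spacing_threshold / eccentricity
}

#' Per-session Bouma factor
#'
#' Aggregates the per-location Bouma factors of one observer-session
#' into a single session estimate by geometric mean.  The study design
#' has 8 locations per session (4 cardinal meridians x 2
#' eccentricities); fewer are tolerated with a warning, since the
#' geometric mean remains well defined over the available locations.
#'
#' @param bouma_factors Numeric vector of per-location Bouma factors,
#'   all > 0.
#' @param expected_locations Number of locations expected per session
#'   (default 8); a deviation triggers a warning, not an error.
#' @return The session Bouma factor (geometric mean).
#' @examples
#' session_bouma(rep(0.3, 8))
#' @export
session_bouma <- function(bouma_factors, expected_locations = 8L) {
  if (length(bouma_factors) == 0L) {
    stop("no Bouma factors supplied for this session")
  }
  if (length(bouma_factors) != expected_locations) {
    warning(sprintf(
      "expected %d locations but got %d; geometric mean over available locations",
      expected_locations, length(bouma_factors)
    ))
  }
  geometric_mean(bouma_factors)
}

#' Combine session Bouma factors into an observer estimate
#'
#' The observer's Bouma factor is the geometric mean of the session
#' estimates; the observer's uncrowded-letter count \eqn{\lambda} is
#' then evaluated from the closed form at the configured field
#' constants (which, unlike the threshold conversion, include `phi0`).
#'
#' @param session_values Numeric vector of 1 or 2 session Bouma
#'   factors.
#' @param phi0,a,phi_max Field constants passed to
#'   [uncrowded_letters()].
#' @return A list of class `"observer_bouma"` with elements
#'   `session_bouma`, `combined_bouma` and `lambda`.
#' @examples
#' observer_bouma(c(0.34, 0.34))$lambda  # ~302 letters
#' @export
observer_bouma <- function(session_values, phi0 = 0.24, a = 2, phi_max = 10) {
  if (!length(session_values) %in% 1:2) {
    stop("'session_values' must hold 1 or 2 session Bouma factors")
  }
  combined <- geometric_mean(session_values)
  lambda <- uncrowded_letters(bouma_params(combined, phi0 = phi0, a = a),
                              phi_max = phi_max)
  structure(
    list(session_bouma = session_values, combined_bouma = combined,
         lambda = lambda),
    class = "observer_bouma"
  )
}

#' @export
print.observer_bouma <- function(x, ...) {
  cat(sprintf(
    "Observer Bouma factor %.3f (sessions: %s); lambda = %.1f letters (~%d)\n",
    x$combined_bouma, paste(sprintf("%.3f", x$session_bouma), collapse = ", "),
    x$lambda, round(x$lambda)
  ))
  invisible(x)
}

#' Per-observer Bouma factors and letter counts from raw thresholds
#'
#' Runs the full psychophysical aggregation over a thresholds table:
#' per-location thresholds are converted to Bouma factors, reduced to
#' one Bouma factor per session by geometric mean, combined across
#' sessions by geometric mean, and converted to \eqn{\lambda} via the
#' closed-form letter count.  Per-session \eqn{\lambda} values are also
#' reported so that test-retest reliability can be assessed.
#'
#' @param thresholds A data frame as returned by [read_thresholds()]
#'   (columns `observer`, `meridian`, `eccentricity_deg`, `session`,
#'   `spacing_threshold_deg`).
#' @inheritParams observer_bouma
#' @return A data frame with one row per observer: `observer`,
#'   `b_session1`, `b_session2`, `b_combined`, `lambda_session1`,
#'   `lambda_session2`, `lambda`.  Session columns are `NA` for
#'   sessions that are absent.
#' @examples
#' pop <- generate_population(population_params(n_observers = 4))
#' compute_bouma_table(pop$thresholds)
#' @export
compute_bouma_table <- function(thresholds, phi0 = 0.24, a = 2,
                                phi_max = 10) {
  thresholds <- validate_thresholds(thresholds)
  observers <- unique(thresholds$observer)
  lam <- function(b) {
    if (is.na(b)) return(NA_real_)
    uncrowded_letters(bouma_params(b, phi0 = phi0, a = a), phi_max = phi_max)
  }
  res <- lapply(observers, function(obs) {
    rows <- thresholds[thresholds$observer == obs, ]
    bs <- vapply(1:2, function(s) {
      sess <- rows[rows$session == s, ]
      if (nrow(sess) == 0L) return(NA_real_)
      session_bouma(bouma_from_threshold(
        sess$spacing_threshold_deg, sess$eccentricity_deg
      ))
    }, numeric(1))
    combined <- geometric_mean(bs[!is.na(bs)])
    data.frame(
      observer = obs,
      b_session1 = bs[1], b_session2 = bs[2], b_combined = combined,
      lambda_session1 = lam(bs[1]), lambda_session2 = lam(bs[2]),
      lambda = lam(combined)
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Test-retest reliability of the letter count
#'
#' Pearson correlation between session-1 and session-2 values across
#' observers, plus the geometric-mean session-2/session-1 ratio (the
#' multiplicative practice effect).  By default reliability is
#' assessed on \eqn{\lambda}; `on = "bouma"` assesses the Bouma factor
#' instead (note \eqn{\lambda \propto b^{-2}}, so a \eqn{\lambda} gain
#' g corresponds to a Bouma ratio \eqn{g^{-1/2}}).
#'
#' @param bouma_table A data frame from [compute_bouma_table()].
#' @param on `"lambda"` (default) or `"bouma"`.
#' @return A list with `r` (Pearson correlation), `session_ratio`
#'   (geometric mean of per-observer session-2/session-1 ratios) and
#'   `n` (number of complete observers).
#' @examples
#' pop <- generate_population(population_params(n_observers = 12))
#' test_retest(compute_bouma_table(pop$thresholds))
#' @export
test_retest <- function(bouma_table, on = c("lambda", "bouma")) {
  on <- match.arg(on)
  cols <- if (on == "lambda") {
    c("lambda_session1", "lambda_session2")
  } else {
    c("b_session1", "b_session2")
  }
  s1 <- bouma_table[[cols[1]]]
  s2 <- bouma_table[[cols[2]]]
  ok <- !is.na(s1) & !is.na(s2)
  if (sum(ok) < 3L) {
    stop("test-retest needs at least 3 observers with both sessions")
  }
  list(
    r = stats::cor(s1[ok], s2[ok]),
    session_ratio = geometric_mean(s2[ok] / s1[ok]),
    n = sum(ok)
  )
}
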