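#' Bouma-law parameters
#'
#' Container for the three constants of the crowding model.  The Bouma
#' law states that the radial crowding distance (critical spacing)
#' grows linearly with eccentricity \eqn{\varphi}:
#' \deqn{s_r = b(\varphi + \varphi_0)}
#' where \eqn{b} is the observer's Bouma factor and \eqn{\varphi_0} a
#' small eccentricity offset that keeps the law affine near the fovea.
#' Crowding zones are radially elongated: the tangential crowding
#' distance is \eqn{s_t = s_r / a} with \eqn{a \approx 2}.
#'
#' @param b Bouma factor (unitless slope of the Bouma law), > 0.
#' @param phi0 Eccentricity offset in degrees, >= 0.  Default 0.24 deg.
#' @param a Radial-to-tangential crowding-distance ratio, > 0.
#'   Default 2.
#' @return An object of class `"bouma_params"`: a list with elements
#'   `b`, `phi0` and `a`.
#' @examples
#' p <- bouma_params(0.34)
#' radial_crowding_distance(p, 10)
#' @export
bouma_params <- function(b, phi0 = 0.24, a = 2) {
  check_scalar(b, "b", 0)
  check_scalar(phi0, "phi0", 0, strict = FALSE)
  check_scalar(a, "a", 0)
  structure(list(b = b, phi0 = phi0, a = a), class = "bouma_params")
}

#' @export
print.bouma_params <- function(x, ...) {
  cat(sprintf(
    "Bouma-law parameters: b = %g, phi0 = %g deg, a = %g\n",
    x$b, x$phi0, x$a
  ))
  invisible(x)
}

as_bouma_params <- function(params) {
  if (!inherits(params, "bouma_params")) {
    stop("'params' must be a 'bouma_params' object; see bouma_params()")
  }
  params
}

check_phi <- function(phi) {
  if (!is.numeric(phi) || any(!is.finite(phi))) {
    stop("'phi' must be finite numeric eccentricities in degrees")
  }
  if (any(phi < 0)) stop("negative eccentricity 'phi' is not allowed")
  phi
}

#' Radial and tangential crowding distance
#'
#' `radial_crowding_distance()` evaluates the Bouma law
#' \eqn{s_r = b(\varphi + \varphi_0)};
#' `tangential_crowding_distance()` returns \eqn{s_t = s_r / a}.
#' Both are vectorised over `phi`.
#'
#' @param params A [bouma_params()] object.
#' @param phi Eccentricity in degrees, >= 0 (vectorised).
#' @return Crowding distance(s) in degrees of visual angle.
#' @examples
#' p <- bouma_params(0.22, phi0 = 0.24, a = 2)
#' radial_crowding_distance(p, 5)      # 1.1528
#' tangential_crowding_distance(p, 5)  # half of that
#' @export
radial_crowding_distance <- function(params, phi) {
  params <- as_bouma_params(params)
  check_phi(phi)
  params$b * (phi + params$phi0)
}

#' @rdname radial_crowding_distance
#' @export
tangential_crowding_distance <- function(params, phi) {
  params <- as_bouma_params(params)
  radial_crowding_distance(params, phi) / params$a
}

#' Local density of uncrowded letters
#'
#' When letters are packed as tightly as possible without crowding, the
#' local density (letters per square degree) is the reciprocal of the
#' product of the radial and tangential crowding distances:
#' \deqn{d(\varphi) = \frac{1}{s_r s_t} = \frac{a}{b^2 (\varphi + \varphi_0)^2}.}
#'
#' @inheritParams radial_crowding_distance
#' @return Density in letters per deg^2 (vectorised over `phi`).
#' @examples
#' letter_density(bouma_params(1, phi0 = 0, a = 1), 1)  # 1
#' @export
letter_density <- function(params, phi) {
  params <- as_bouma_params(params)
  check_phi(phi)
  if (any(phi + params$phi0 <= 0)) {
    stop("letter density is singular at phi + phi0 = 0")
  }
  params$a / (params$b^2 * (phi + params$phi0)^2)
}

# The bracketed eccentricity term of the closed-form letter count:
# integral of phi/(phi+phi0)^2 from 0 to phi_max
# = ln(1 + phi_max/phi0) - 1/(1 + phi0/phi_max).
lambda_bracket <- function(phi0, phi_max) {
  log(1 + phi_max / phi0) - 1 / (1 + phi0 / phi_max)
}

#' Number of letters in the uncrowded visual field (closed form)
#'
#' Integrates the uncrowded letter density over a disk of radius
#' `phi_max`, giving the number of letters \eqn{\lambda} that fit in
#' the visual field when spaced at the crowding distance everywhere:
#' \deqn{\lambda = \frac{2\pi a}{b^2}\left[\ln\!\left(1 + \frac{\varphi_{max}}{\varphi_0}\right) - \frac{1}{1 + \varphi_0/\varphi_{max}}\right].}
#' The angular integral is exact (a factor \eqn{2\pi}); the radial
#' integral \eqn{\int_0^{\varphi_{max}} \varphi/(\varphi+\varphi_0)^2\,d\varphi}
#' has the bracketed antiderivative above.  At the default constants
#' (`phi0 = 0.24`, `a = 2`, `phi_max = 10`) this reduces to
#' \eqn{\lambda = 34.9\, b^{-2}}.
#'
#' \eqn{\lambda} is returned as a real number; round to the nearest
#' integer when reporting a letter count.
#'
#' @inheritParams radial_crowding_distance
#' @param phi_max Maximum eccentricity of the visual field in degrees,
#'   > 0.  Default 10 deg, matching typical psychophysics and
#'   retinotopy coverage.
#' @return The letter count \eqn{\lambda} (real, > 0).
#' @seealso [uncrowded_letters_numeric()] for the quadrature
#'   counterpart used as an independent check.
#' @examples
#' round(uncrowded_letters(bouma_params(0.34)))  # 302
#' uncrowded_letters(bouma_params(1))            # ~34.9
#' @export
uncrowded_letters <- function(params, phi_max = 10) {
  params <- as_bouma_params(params)
  check_scalar(phi_max, "phi_max", 0)
  if (params$phi0 <= 0) {
    stop(
      "the closed-form letter count diverges logarithmically as phi0 -> 0; ",
      "phi0 must be > 0"
    )
  }
  2 * pi * params$a / params$b^2 * lambda_bracket(params$phi0, phi_max)
}

#' Number of uncrowded letters by numerical quadrature
#'
#' Computes \eqn{\lambda} as the radial quadrature
#' \eqn{2\pi \int_{\varphi_{min}}^{\varphi_{max}} \varphi\, d(\varphi)\, d\varphi}
#' of [letter_density()].  This route is deliberately independent of
#' the closed form and serves as its oracle in the test suite; the two
#' agree to the quadrature tolerance.
#'
#' @inheritParams uncrowded_letters
#' @param phi_min Inner integration radius in degrees.  Must be > 0
#'   when `phi0 = 0`, where the density is non-integrable at the
#'   fovea.  Default 0.
#' @param rel_tol Relative accuracy requested from [stats::integrate()].
#' @return The letter count \eqn{\lambda} (real).
#' @examples
#' uncrowded_letters_numeric(bouma_params(0.34))  # ~301.86
#' @export
uncrowded_letters_numeric <- function(params, phi_max = 10, phi_min = 0,
                                      rel_tol = 1e-10) {
  params <- as_bouma_params(params)
  check_scalar(phi_max, "phi_max", 0)
  check_scalar(phi_min, "phi_min", 0, strict = FALSE)
  if (phi_min >= phi_max) stop("'phi_min' must be smaller than 'phi_max'")
  if (params$phi0 <= 0 && phi_min <= 0) {
    stop(
      "with phi0 = 0 the density is non-integrable at the fovea; ",
      "supply a positive 'phi_min'"
    )
  }
  q <- stats::integrate(
    function(phi) phi * letter_density(params, phi),
    lower = phi_min, upper = phi_max, rel.tol = rel_tol
  )
  if (q$message != "OK") {
    stop("quadrature did not converge: ", q$message)
  }
  2 * pi * q$value
}

#' Sensitivity of the letter count to the field constants
#'
#' Quantifies how \eqn{\lambda} (and hence the cortical crowding
#' distance \eqn{c} implied by a conservation fit with map areas held
#' fixed) would change under alternative values of `phi0`, `a`, or
#' `phi_max`.  Because \eqn{\lambda} is linear in \eqn{a} and the
#' eccentricity term enters as a single bracket, each alternative value
#' yields a pure multiplier on \eqn{\lambda}; since \eqn{c \propto
#' \lambda^{-1/2}} at fixed areas, the implied multiplier on \eqn{c}
#' is the inverse square root.
#'
#' @inheritParams uncrowded_letters
#' @param phi0_values,a_values,phi_max_values Numeric vectors of
#'   alternative constants to evaluate (any may be `NULL`).
#' @return A data frame with columns `parameter`, `baseline`, `value`,
#'   `lambda_multiplier` and `c_multiplier`, one row per alternative
#'   setting.
#' @examples
#' p <- bouma_params(0.3)
#' lambda_sensitivity(p, a_values = 4)  # lambda x2, c x 1/sqrt(2)
#' @export
lambda_sensitivity <- function(params, phi_max = 10, phi0_values = NULL,
                               a_values = NULL, phi_max_values = NULL) {
  params <- as_bouma_params(params)
  base <- uncrowded_letters(params, phi_max)
  rows <- list()
  add <- function(parameter, baseline, value, alt_lambda) {
    mult <- alt_lambda / base
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, baseline = baseline, value = value,
      lambda_multiplier = mult, c_multiplier = mult^(-0.5)
    )
  }
  for (v in phi0_values) {
    alt <- bouma_params(params$b, phi0 = v, a = params$a)
    add("phi0", params$phi0, v, uncrowded_letters(alt, phi_max))
  }
  for (v in a_values) {
    alt <- bouma_params(params$b, phi0 = params$phi0, a = v)
    add("a", params$a, v, uncrowded_letters(alt, phi_max))
  }
  for (v in phi_max_values) {
    check_scalar(v, "phi_max_values", 0)
    add("phi_max", phi_max, v, uncrowded_letters(params, v))
  }
  if (length(rows) == 0L) {
    return(data.frame(
      parameter = character(), baseline = numeric(), value = numeric(),
      lambda_multiplier = numeric(), c_multiplier = numeric()
    ))
  }
  do.call(rbind, rows)
}

#' Lay letters out at threshold spacing
#'
#' Produces letter positions packed at the local crowding distance in a
#' sector of the visual field, for visualisation of the uncrowded
#' field.  Rings are placed greedily from the inner sector edge: each
#' ring's centre eccentricity \eqn{\varphi_c} satisfies
#' \eqn{\varphi_c = e_0 + s_r(\varphi_c)/2} so that adjacent rings are
#' separated radially by the local radial crowding distance, and
#' within-ring neighbours are separated by the local tangential
#' crowding distance (the per-ring letter count is floored).  Over the
#' full field the total count approximates the continuous
#' [uncrowded_letters()] value, up to discretisation.
#'
#' @inheritParams uncrowded_letters
#' @param ecc_range Eccentricity interval `c(min, max)` of the sector,
#'   in degrees, within `[0, phi_max]`.
#' @param angle_range Polar-angle interval `c(min, max)` of the sector,
#'   in radians; width at most `2*pi`.
#' @return A data frame with columns `eccentricity_deg` and
#'   `angle_rad`, one row per letter (possibly zero rows).
#' @examples
#' nrow(letter_layout(bouma_params(0.34)))  # close to 302
#' @export
letter_layout <- function(params, phi_max = 10,
                          ecc_range = c(0, phi_max),
                          angle_range = c(0, 2 * pi)) {
  params <- as_bouma_params(params)
  check_scalar(phi_max, "phi_max", 0)
  stopifnot(length(ecc_range) == 2L, length(angle_range) == 2L)
  if (ecc_range[1] < 0 || ecc_range[2] > phi_max) {
    stop("'ecc_range' must lie within [0, phi_max]")
  }
  if (params$b >= 2) {
    stop("ring construction requires b < 2 (crowding distance growing slower than eccentricity doubles)")
  }
  width <- angle_range[2] - angle_range[1]
  if (width < 0 || width > 2 * pi + 1e-12) {
    stop("'angle_range' must be increasing with width at most 2*pi")
  }
  empty <- data.frame(eccentricity_deg = numeric(), angle_rad = numeric())
  if (width == 0 || ecc_range[1] >= ecc_range[2]) return(empty)

  b <- params$b
  phi0 <- params$phi0
  ecc <- numeric()
  ang <- numeric()
  e0 <- ecc_range[1]
  repeat {
    # ring centre: phi_c = e0 + b*(phi_c + phi0)/2, solved linearly
    phi_c <- (e0 + b * phi0 / 2) / (1 - b / 2)
    s_r <- radial_crowding_distance(params, phi_c)
    # a ring belongs to the sector if its centre does; cutting at the
    # ring's outer edge instead would drop most of an outer annulus
    # and bias the count low when crowding distances are large
    if (phi_c > ecc_range[2] + 1e-12) break
    s_t <- s_r / params$a
    n <- floor(width * phi_c / s_t)
    if (n >= 1) {
      step <- width / n
      ecc <- c(ecc, rep(phi_c, n))
      ang <- c(ang, angle_range[1] + (seq_len(n) - 0.5) * step)
    }
    e0 <- phi_c + s_r / 2
  }
  data.frame(eccentricity_deg = ecc, angle_rad = ang)
}
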