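#' QUEST staircase configuration
#'
#' Settings for the Bayesian adaptive staircase used to simulate a
#' crowding-threshold measurement.  The psychometric function is a
#' Weibull on log10 spacing,
#' \deqn{\psi(x) = \delta\gamma + (1-\delta)\left[1 - (1-\gamma)
#'   e^{-10^{\beta (x - T)}}\right],}
#' where \eqn{x} is the tested log10 spacing, \eqn{T} the true log10
#' threshold, \eqn{\gamma} the guessing rate (reciprocal of the
#' response-alphabet size, typically 9 letters), \eqn{\delta} the
#' lapse ("finger error") rate, and \eqn{\beta} the slope.  The
#' staircase maintains a posterior over \eqn{T} on a discrete grid,
#' tests each trial at the posterior mode, and reports the posterior
#' mean.
#'
#' @param n_trials Trials per threshold estimate (default 35).
#' @param guess_rate \eqn{\gamma}, probability of a correct guess
#'   (default 1/9).
#' @param lapse_rate \eqn{\delta}, lapse probability (default 0.01).
#' @param prior_mean,prior_sd Gaussian prior over log10 threshold
#'   spacing (deg).  The default prior mean corresponds to a 1.5 deg
#'   spacing guess; set it per condition (e.g. to the Bouma-law
#'   expectation at the tested eccentricity).
#' @param slope Weibull slope \eqn{\beta} on log10 spacing (default
#'   2.3, conventional for letter identification).
#' @param grid_range Half-width of the log10 grid around `prior_mean`.
#' @param grid_step Grid resolution in log10 units.
#' @param seed Optional integer seed for the simulated responses.
#' @return A list of class `"quest_config"`.
#' @export
quest_config <- function(n_trials = 35, guess_rate = 1 / 9,
                         lapse_rate = 0.01, prior_mean = log10(1.5),
                         prior_sd = 0.6, slope = 2.3, grid_range = 2.5,
                         grid_step = 0.01, seed = NULL) {
  check_scalar(n_trials, "n_trials", 0)
  if (guess_rate < 0 || guess_rate >= 1) stop("'guess_rate' must be in [0, 1)")
  if (lapse_rate < 0 || lapse_rate >= 1) stop("'lapse_rate' must be in [0, 1)")
  check_scalar(prior_sd, "prior_sd", 0)
  check_scalar(slope, "slope", 0)
  check_scalar(grid_range, "grid_range", 0)
  check_scalar(grid_step, "grid_step", 0)
  structure(
    list(n_trials = as.integer(n_trials), guess_rate = guess_rate,
         lapse_rate = lapse_rate, prior_mean = prior_mean,
         prior_sd = prior_sd, slope = slope, grid_range = grid_range,
         grid_step = grid_step, seed = seed),
    class = "quest_config"
  )
}

# Weibull psychometric function on log10 spacing.
quest_psi <- function(x, threshold_log10, guess_rate, lapse_rate, slope) {
  lapse_rate * guess_rate + (1 - lapse_rate) *
    (1 - (1 - guess_rate) * exp(-10^(slope * (x - threshold_log10))))
}

#' Simulate one QUEST threshold run
#'
#' Runs a trial-level Bayesian adaptive staircase against a simulated
#' observer whose true threshold is `true_threshold`.  Each trial is
#' presented at the current posterior mode over log10 threshold, the
#' response is drawn as a Bernoulli with probability given by the
#' Weibull psychometric function evaluated at the true threshold, and
#' the posterior is updated by Bayes' rule on the discrete grid.  The
#' final threshold estimate is the posterior mean (in log10, then
#' exponentiated).
#'
#' @param true_threshold The simulated observer's true spacing
#'   threshold in degrees, > 0.
#' @param config A [quest_config()].
#' @param seed Integer seed for the response sequence; defaults to
#'   `config$seed`.  The same seed reproduces the identical trial
#'   sequence and estimate.
#' @return A list with `threshold` (deg), `log10_threshold`, and
#'   `trials` (data frame of tested log10 spacings and responses).
#' @examples
#' simulate_quest_run(1.1, quest_config(seed = 1))$threshold
#' @export
simulate_quest_run <- function(true_threshold, config = quest_config(),
                               seed = config$seed) {
  check_scalar(true_threshold, "true_threshold", 0)
  grid <- seq(config$prior_mean - config$grid_range,
              config$prior_mean + config$grid_range,
              by = config$grid_step)
  if (length(grid) < 3L) {
    stop("degenerate posterior grid; widen 'grid_range' or shrink 'grid_step'")
  }
  posterior <- stats::dnorm(grid, config$prior_mean, config$prior_sd)
  posterior <- posterior / sum(posterior)
  t_true <- log10(true_threshold)

  with_seed(seed, {
    x_seq <- numeric(config$n_trials)
    resp_seq <- logical(config$n_trials)
    for (trial in seq_len(config$n_trials)) {
      x <- grid[which.max(posterior)]
      p_correct <- quest_psi(x, t_true, config$guess_rate,
                             config$lapse_rate, config$slope)
      correct <- stats::runif(1) < p_correct
      p_grid <- quest_psi(x, grid, config$guess_rate,
                          config$lapse_rate, config$slope)
      posterior <- posterior * if (correct) p_grid else 1 - p_grid
      total <- sum(posterior)
      if (total <= 0) {
        # a zero-likelihood observation (possible only with gamma = 0,
        # delta = 0 and a saturated psychometric function): restart
        # from the prior rather than leave an improper posterior
        posterior <- stats::dnorm(grid, config$prior_mean, config$prior_sd)
        posterior <- posterior / sum(posterior)
      } else {
        posterior <- posterior / total
      }
      x_seq[trial] <- x
      resp_seq[trial] <- correct
    }
    est <- sum(grid * posterior)
    list(
      threshold = 10^est, log10_threshold = est,
      trials = data.frame(log10_spacing = x_seq, correct = resp_seq)
    )
  })
}
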