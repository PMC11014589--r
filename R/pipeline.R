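#' Pipeline configuration
#'
#' Bundles the constants every stage of the analysis shares: the
#' visual-field constants used to turn Bouma factors into letter
#' counts, and the bootstrap settings for the conservation fits.  The
#' effective configuration is echoed into every report so each
#' reported quantity is traceable to the constants that produced it.
#'
#' @param phi0 Eccentricity offset of the Bouma law, deg (default
#'   0.24).
#' @param a Radial-to-tangential crowding ratio (default 2).
#' @param phi_max Maximum eccentricity of the analysed field, deg
#'   (default 10).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param conf_levels Bootstrap interval levels (default 68% and 95%).
#' @param seed Integer seed for the bootstrap.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(phi0 = 0.24, a = 2, phi_max = 10,
                            n_boot = 10000, conf_levels = c(0.68, 0.95),
                            seed = 1L) {
  check_scalar(phi0, "phi0", 0)
  check_scalar(a, "a", 0)
  check_scalar(phi_max, "phi_max", 0)
  check_scalar(n_boot, "n_boot", 0, strict = FALSE)
  structure(
    list(phi0 = phi0, a = a, phi_max = phi_max,
         n_boot = as.integer(n_boot), conf_levels = conf_levels,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the complete crowding-conservation analysis
#'
#' Ties the stages together: read (or accept) the thresholds and areas
#' tables, convert thresholds to per-observer Bouma factors and letter
#' counts, assess test-retest reliability, fit the conservation model
#' to every map with bootstrap intervals, and assemble a report.  The
#' run is deterministic given the configuration seed.
#'
#' @param thresholds A thresholds data frame or a path to a thresholds
#'   CSV (see [read_thresholds()]).
#' @param areas A long or wide areas data frame or a path to an areas
#'   CSV (see [read_areas()]).
#' @param config A [pipeline_config()].
#' @param out Optional path for a JSON report.
#' @return A list of class `"pipeline_report"`: `config` (echoed),
#'   `n_observers`, `bouma_table`, `test_retest` (NULL when fewer
#'   than 3 complete observers), `maps` (the [map_comparison()]
#'   table), and `best_map`.
#' @examples
#' pop <- generate_population(population_params(n_observers = 8))
#' rep <- run_pipeline(pop$thresholds, pop$areas,
#'                     pipeline_config(n_boot = 200))
#' rep$best_map
#' @export
run_pipeline <- function(thresholds, areas, config = pipeline_config(),
                         out = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(thresholds)) thresholds <- read_thresholds(thresholds)
  thresholds <- validate_thresholds(thresholds)
  if (is.character(areas)) areas <- read_areas(areas)

  message(sprintf("thresholds: %d rows, %d observer(s)", nrow(thresholds),
                  length(unique(thresholds$observer))))
  tab <- compute_bouma_table(thresholds, phi0 = config$phi0, a = config$a,
                             phi_max = config$phi_max)
  complete <- sum(!is.na(tab$lambda_session1) & !is.na(tab$lambda_session2))
  tr <- if (complete >= 3L) test_retest(tab) else NULL
  cohort <- build_cohort(tab, areas)
  message(sprintf("cohort: %d observer(s) with behaviour and areas",
                  nrow(cohort)))
  maps_present <- intersect(VISUAL_MAPS, names(cohort))
  maps <- map_comparison(cohort, maps = maps_present, n_boot = config$n_boot,
                         conf_levels = config$conf_levels,
                         seed = config$seed)
  report <- structure(
    list(
      config = unclass(config),
      n_observers = nrow(cohort),
      bouma_table = tab,
      test_retest = tr,
      maps = maps,
      best_map = maps$map[maps$best][1]
    ),
    class = "pipeline_report"
  )
  if (!is.null(out)) {
    jsonlite::write_json(
      report[c("config", "n_observers", "test_retest", "maps", "best_map")],
      out, auto_unbox = TRUE, digits = 10, dataframe = "rows"
    )
    message("report written to ", out)
  }
  report
}

#' @export
print.pipeline_report <- function(x, digits = 2, ...) {
  cat(sprintf("Crowding-conservation pipeline report (%d observers)\n",
              x$n_observers))
  if (!is.null(x$test_retest)) {
    cat(sprintf(
      "  test-retest of lambda: r = %.2f, session-2/session-1 ratio = %.2f (n = %d)\n",
      x$test_retest$r, x$test_retest$session_ratio, x$test_retest$n
    ))
  }
  cols <- intersect(c("map", "k", "c", "r", "r_squared"), names(x$maps))
  tab <- x$maps[, cols]
  print(tab, digits = digits + 1, row.names = FALSE)
  cat(sprintf("  best map by variance explained: %s (c = %.2f mm)\n",
              x$best_map, x$maps$c[x$maps$best][1]))
  invisible(x)
}
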