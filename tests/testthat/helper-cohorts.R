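# Fixtures built in code.

# the two worked-example observers: letter counts and bilateral map
# areas (mm^2)
table2_cohort <- function() {
  data.frame(
    observer = c("Observer 1", "Observer 2"),
    lambda = c(748, 302),
    V1 = c(3052, 2580), V2 = c(2767, 2815),
    V3 = c(2053, 1907), V4 = c(1483, 618)
  )
}

# a cohort lying exactly on lambda = k * area
line_cohort <- function(k, areas = c(500, 900, 1300, 2000)) {
  data.frame(observer = seq_along(areas), lambda = k * areas, V4 = areas)
}

# 16 thresholds generated exactly on the Bouma law (no phi0, as in the
# threshold-to-Bouma conversion) for one observer
exact_thresholds <- function(b, observer = "obs") {
  grid <- expand.grid(
    session = 1:2, eccentricity_deg = c(5, 10),
    meridian = c("upper", "lower", "left", "right"),
    stringsAsFactors = FALSE
  )
  data.frame(
    observer = observer, meridian = grid$meridian,
    eccentricity_deg = grid$eccentricity_deg, session = grid$session,
    spacing_threshold_deg = b * grid$eccentricity_deg
  )
}

noise_free_params <- function(n = 49, seed = 11) {
  population_params(
    n_observers = n, threshold_noise_log_sd = 0,
    session2_lambda_gain = 1, v4_area_log_noise_sd = 0, seed = seed
  )
}
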