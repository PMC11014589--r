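# CSV input/output.  All files are comma-separated UTF-8 with a
# mandatory header and dot decimals; units are embedded in column
# names (degrees of visual angle, mm^2).

# shared validation for a thresholds data frame; returns it with
# canonical column order
validate_thresholds <- function(df, file = NULL) {
  required <- c("observer", "meridian", "eccentricity_deg", "session",
                "spacing_threshold_deg")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("thresholds table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  where <- function(i) {
    if (is.null(file)) sprintf("row %d", i) else sprintf("%s line %d", file, i + 1L)
  }
  bad <- which(!df$meridian %in% MERIDIANS)
  if (length(bad)) {
    stop(sprintf("unknown meridian %s at %s (allowed: %s)",
                 dQuote(df$meridian[bad[1]]), where(bad[1]),
                 paste(MERIDIANS, collapse = ", ")))
  }
  bad <- which(!is.finite(df$spacing_threshold_deg) |
                 df$spacing_threshold_deg <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive spacing threshold at %s", where(bad[1])))
  }
  bad <- which(!is.finite(df$eccentricity_deg) | df$eccentricity_deg <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive eccentricity at %s", where(bad[1])))
  }
  bad <- which(!df$session %in% c(1L, 2L))
  if (length(bad)) {
    stop(sprintf("session must be 1 or 2 at %s", where(bad[1])))
  }
  df$observer <- as.character(df$observer)
  df[, required]
}

#' Read and write crowding-threshold tables
#'
#' `read_thresholds()` loads a CSV of spacing thresholds with columns
#' `observer`, `meridian` (upper/lower/left/right), `eccentricity_deg`,
#' `session` (1 or 2) and `spacing_threshold_deg`, validating every
#' row (malformed rows are reported with their line number).
#' `write_thresholds()` writes the same format; the pair round-trips
#' losslessly.
#'
#' @param path Path to the CSV file.
#' @return For `read_thresholds()`, a validated data frame.
#' @export
read_thresholds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_thresholds(df, file = path)
}

#' @rdname read_thresholds
#' @param thresholds A thresholds data frame.
#' @export
write_thresholds <- function(thresholds, path) {
  thresholds <- validate_thresholds(thresholds)
  utils::write.csv(thresholds, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# collapse a long (observer, map, hemisphere, area_mm2) table to a
# wide bilateral table, warning about single-hemisphere entries
sum_hemispheres <- function(df) {
  key <- paste(df$observer, df$map, df$hemisphere, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop(sprintf("duplicate observer-map-hemisphere row(s), e.g. %s %s %s",
                 df$observer[dup][1], df$map[dup][1], df$hemisphere[dup][1]))
  }
  counts <- stats::aggregate(hemisphere ~ observer + map, df, length)
  single <- counts[counts$hemisphere < 2L, ]
  if (nrow(single)) {
    warning(sprintf(
      "single-hemisphere area for %d observer-map pair(s) (e.g. %s %s); using the one hemisphere",
      nrow(single), single$observer[1], single$map[1]
    ))
  }
  agg <- stats::aggregate(area_mm2 ~ observer + map, df, sum)
  wide <- stats::reshape(agg, idvar = "observer", timevar = "map",
                         direction = "wide")
  names(wide) <- sub("^area_mm2\\.", "", names(wide))
  missing_map <- setdiff(VISUAL_MAPS, names(wide))
  incomplete <- rowSums(is.na(wide[, intersect(VISUAL_MAPS, names(wide)),
                                   drop = FALSE])) > 0
  if (length(missing_map) || any(incomplete)) {
    warning(sprintf("%d observer(s) missing at least one map area",
                    max(sum(incomplete), length(missing_map) > 0)))
  }
  rownames(wide) <- NULL
  attr(wide, "single_hemisphere") <- single[, c("observer", "map")]
  wide
}

#' Read and write retinotopic map areas
#'
#' `read_areas()` loads a long CSV with columns `observer`, `map`
#' (V1-V4), `hemisphere` (L/R) and `area_mm2`, rejects duplicated
#' observer-map-hemisphere rows, sums areas across hemispheres
#' (bilateral areas are what the conservation analysis uses; a
#' missing hemisphere raises a warning and the pair is flagged in the
#' `"single_hemisphere"` attribute), and returns one row per observer
#' with one column per map.  `write_areas()` writes the long format.
#'
#' @param path Path to the CSV file.
#' @return For `read_areas()`, a wide data frame (`observer`,
#'   `V1`..`V4`) with attribute `"single_hemisphere"`.
#' @export
read_areas <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("observer", "map", "hemisphere", "area_mm2")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("areas table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!df$map %in% VISUAL_MAPS)
  if (length(bad)) {
    stop(sprintf("unknown map %s at %s line %d", dQuote(df$map[bad[1]]),
                 path, bad[1] + 1L))
  }
  bad <- which(!df$hemisphere %in% c("L", "R"))
  if (length(bad)) {
    stop(sprintf("hemisphere must be L or R at %s line %d", path,
                 bad[1] + 1L))
  }
  bad <- which(!is.finite(df$area_mm2) | df$area_mm2 <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive area at %s line %d", path, bad[1] + 1L))
  }
  df$observer <- as.character(df$observer)
  sum_hemispheres(df)
}

#' @rdname read_areas
#' @param areas A long areas data frame (`observer`, `map`,
#'   `hemisphere`, `area_mm2`).
#' @export
write_areas <- function(areas, path) {
  stopifnot(all(c("observer", "map", "hemisphere", "area_mm2") %in%
                  names(areas)))
  utils::write.csv(areas, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Writes the thresholds CSV and areas CSV in exactly the formats the
#' analysis reads, plus a ground-truth JSON (true Bouma factors, true
#' areas, `c_true` and the seed) for later comparison with recovered
#' values.
#'
#' @param pop A [generate_population()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_population <- function(pop, dir) {
  stopifnot(inherits(pop, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    thresholds = file.path(dir, "thresholds.csv"),
    areas = file.path(dir, "areas.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_thresholds(pop$thresholds, paths["thresholds"])
  write_areas(pop$areas, paths["areas"])
  jsonlite::write_json(
    list(
      c_true = pop$params$c_true, seed = pop$params$seed,
      params = unclass(pop$params),
      truth = pop$truth
    ),
    paths["truth"], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
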