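# Data model and validated CSV readers/writers for all tabular inputs.
#
# All readers return tibbles; all writers accept the same tibbles, so a
# write-then-read round trip reproduces every record field-for-field.

PLANT_PARTS <- c(
  "young_leaf", "mature_leaf", "ripe_fruit", "unripe_fruit",
  "ripe_pod", "unripe_pod", "bud", "flower"
)

#' Construct a scan-record table
#'
#' One row per 2-hourly scan sample: the focal core unit plus the set of
#' units recorded within the association radius. `associates` is a
#' list-column of character vectors (possibly empty).
#'
#' @param date `Date` vector.
#' @param time character `"HH:MM"` (24 h).
#' @param focal_unit character unit identifiers.
#' @param associates list of character vectors; a unit never associates with
#'   itself, so the focal must not appear in its own associate set.
#' @return a tibble with columns `date`, `time`, `focal_unit`, `associates`.
#' @export
scan_table <- function(date, time, focal_unit, associates) {
  if (!is.list(associates)) associates <- list(associates)
  tibble::tibble(
    date = as.Date(date),
    time = as.character(time),
    focal_unit = as.character(focal_unit),
    associates = lapply(associates, function(a) unique(as.character(a[nzchar(a)])))
  )
}

validate_scans <- function(scans, strict = TRUE) {
  bad <- rep("", nrow(scans))
  if (anyNA(scans$date)) bad[is.na(scans$date)] <- "malformed date"
  mins <- time_minutes(scans$time)
  bad[bad == "" & is.na(mins)] <- "malformed time"
  if (strict) {
    outside <- !is.na(mins) & (mins < 7 * 60 | mins > 16 * 60)
    bad[bad == "" & outside] <- "time outside 07:00-16:00"
  }
  empty_focal <- is.na(scans$focal_unit) | !nzchar(scans$focal_unit)
  bad[bad == "" & empty_focal] <- "empty focal unit"
  self <- mapply(function(f, a) f %in% a, scans$focal_unit, scans$associates,
                 USE.NAMES = FALSE)
  bad[bad == "" & self] <- "focal listed among its own associates"
  bad
}

#' Read and write scan samples
#'
#' `scans.csv` columns: `date,time,focal_unit,associates`, with the associate
#' list semicolon-separated inside one cell (ISO-8601 dates, 24 h times).
#' Under `strict = TRUE` any invalid row is an error; otherwise invalid rows
#' are dropped with a warning naming each offence.
#'
#' Scans of the same focal taken less than 2 h apart violate the sampling
#' design's independence rule; they are kept but flagged with a warning.
#'
#' @param path file path.
#' @param strict validate strictly (error on bad rows) or leniently (skip).
#' @return `read_scans()`: a scan tibble (see [scan_table()]).
#' @export
read_scans <- function(path, strict = TRUE) {
  raw <- read_csv_checked(path, c("date", "time", "focal_unit", "associates"))
  scans <- scan_table(
    date = suppressWarnings(as.Date(raw$date, format = "%Y-%m-%d")),
    time = raw$time,
    focal_unit = raw$focal_unit,
    associates = split_assoc(raw$associates)
  )
  scans <- drop_or_fail(scans, validate_scans(scans, strict = strict), strict, path)
  warn_close_scans(scans)
  scans
}

split_assoc <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE), function(a) trimws(a[nzchar(trimws(a))]))
}

warn_close_scans <- function(scans) {
  if (nrow(scans) < 2) return(invisible(scans))
  key <- paste(scans$focal_unit, scans$date)
  mins <- time_minutes(scans$time)
  close <- unlist(lapply(split(mins, key), function(m) {
    m <- sort(m)
    length(m) > 1 && any(diff(m) < 120)
  }))
  if (any(close)) {
    warning(sprintf(
      "%d focal-day(s) contain scans of the same focal < 2 h apart", sum(close)
    ), call. = FALSE)
  }
  invisible(scans)
}

#' @rdname read_scans
#' @param scans scan tibble.
#' @export
write_scans <- function(scans, path) {
  out <- data.frame(
    date = format(scans$date, "%Y-%m-%d"),
    time = scans$time,
    focal_unit = scans$focal_unit,
    associates = vapply(scans$associates, paste, "", collapse = ";")
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write monthly phenology scores
#'
#' `phenology.csv` columns: `tree_id,species,month,plant_part,score`; the
#' score is the five-point canopy-cover scale 0 (part absent) to 4
#' (76-100% cover); `plant_part` is one of
#' `r paste(PLANT_PARTS, collapse = ", ")`.
#'
#' @inheritParams read_scans
#' @return a tibble of validated phenology records.
#' @export
read_phenology <- function(path, strict = TRUE) {
  raw <- read_csv_checked(path, c("tree_id", "species", "month", "plant_part", "score"))
  ph <- tibble::tibble(
    tree_id = as.character(raw$tree_id),
    species = as.character(raw$species),
    month = as.character(raw$month),
    plant_part = as.character(raw$plant_part),
    score = suppressWarnings(as.integer(raw$score))
  )
  bad <- rep("", nrow(ph))
  bad[!is_year_month(ph$month)] <- "malformed month"
  bad[bad == "" & !ph$plant_part %in% PLANT_PARTS] <- "unknown plant part"
  score_ok <- !is.na(ph$score) & ph$score >= 0L & ph$score <= 4L
  bad[bad == "" & !score_ok] <- "score outside 0-4"
  drop_or_fail(ph, bad, strict, path)
}

#' @rdname read_phenology
#' @param phenology phenology tibble.
#' @export
write_phenology <- function(phenology, path) {
  utils::write.csv(as.data.frame(phenology), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write species basal areas
#'
#' `basal_area.csv` columns: `species,basal_area_m2` (total over surveyed
#' transects; strictly positive).
#'
#' @inheritParams read_scans
#' @export
read_basal_areas <- function(path, strict = TRUE) {
  raw <- read_csv_checked(path, c("species", "basal_area_m2"))
  ba <- tibble::tibble(
    species = as.character(raw$species),
    basal_area_m2 = suppressWarnings(as.numeric(raw$basal_area_m2))
  )
  bad <- rep("", nrow(ba))
  bad[is.na(ba$basal_area_m2) | ba$basal_area_m2 <= 0] <- "non-positive basal area"
  drop_or_fail(ba, bad, strict, path)
}

#' @rdname read_basal_areas
#' @param basal_areas basal-area tibble.
#' @export
write_basal_areas <- function(basal_areas, path) {
  utils::write.csv(as.data.frame(basal_areas), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write monthly rainfall
#'
#' `rainfall.csv` columns: `month,rainfall_mm` (non-negative).
#'
#' @inheritParams read_scans
#' @export
read_rainfall <- function(path, strict = TRUE) {
  raw <- read_csv_checked(path, c("month", "rainfall_mm"))
  rf <- tibble::tibble(
    month = as.character(raw$month),
    rainfall_mm = suppressWarnings(as.numeric(raw$rainfall_mm))
  )
  bad <- rep("", nrow(rf))
  bad[!is_year_month(rf$month)] <- "malformed month"
  bad[bad == "" & (is.na(rf$rainfall_mm) | rf$rainfall_mm < 0)] <- "negative rainfall"
  drop_or_fail(rf, bad, strict, path)
}

#' @rdname read_rainfall
#' @param rainfall rainfall tibble.
#' @export
write_rainfall <- function(rainfall, path) {
  utils::write.csv(as.data.frame(rainfall), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write dispersal events
#'
#' `dispersals.csv` columns:
#' `individual_id,sex,from_unit,to_unit,last_seen_origin,first_seen_destination`.
#' One row per dispersing individual; a parallel transfer of several males is
#' several rows sharing units and dates. The date range
#' `[last_seen_origin, first_seen_destination]` brackets the (unobserved)
#' transfer; [assign_dispersal_month()] resolves it to a calendar month.
#'
#' @inheritParams read_scans
#' @export
read_dispersals <- function(path, strict = TRUE) {
  raw <- read_csv_checked(path, c(
    "individual_id", "sex", "from_unit", "to_unit",
    "last_seen_origin", "first_seen_destination"
  ))
  ev <- tibble::tibble(
    individual_id = as.character(raw$individual_id),
    sex = as.character(raw$sex),
    from_unit = as.character(raw$from_unit),
    to_unit = as.character(raw$to_unit),
    last_seen_origin = suppressWarnings(as.Date(raw$last_seen_origin)),
    first_seen_destination = suppressWarnings(as.Date(raw$first_seen_destination))
  )
  bad <- rep("", nrow(ev))
  bad[!ev$sex %in% c("male", "female")] <- "sex must be male or female"
  bad[bad == "" & ev$from_unit == ev$to_unit] <- "from_unit equals to_unit"
  dates_na <- is.na(ev$last_seen_origin) | is.na(ev$first_seen_destination)
  bad[bad == "" & dates_na] <- "malformed date"
  inverted <- !dates_na & ev$last_seen_origin > ev$first_seen_destination
  bad[bad == "" & inverted] <- "date-range inversion"
  drop_or_fail(ev, bad, strict, path)
}

#' @rdname read_dispersals
#' @param dispersals dispersal tibble.
#' @export
write_dispersals <- function(dispersals, path) {
  out <- as.data.frame(dispersals[, c(
    "individual_id", "sex", "from_unit", "to_unit",
    "last_seen_origin", "first_seen_destination"
  )])
  out$last_seen_origin <- format(out$last_seen_origin, "%Y-%m-%d")
  out$first_seen_destination <- format(out$first_seen_destination, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_checked <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(columns, names(raw))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", path, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  raw
}

drop_or_fail <- function(df, bad, strict, path) {
  offending <- which(nzchar(bad))
  if (!length(offending)) return(df)
  msg <- sprintf("row %d: %s", offending, bad[offending])
  if (strict) {
    stop(paste0(path, ": invalid rows\n", paste(msg, collapse = "\n")), call. = FALSE)
  }
  warning(sprintf("%s: skipped %d invalid row(s)\n%s", path, length(offending),
                  paste(utils::head(msg, 10L), collapse = "\n")), call. = FALSE)
  df[-offending, , drop = FALSE]
}

#' Study configuration
#'
#' Bundles the analysis constants used across the pipeline: the sliding
#' window geometry (31-day window and shift), the clan cutoff on the AI
#' scale (0.05), the permutation and bootstrap effort (10,000 and 100), the
#' significance level, and the run seed.
#'
#' @param window_days,shift_days sliding-window size and shift, days.
#' @param clan_cutoff AI threshold defining clan co-membership, in (0, 1).
#' @param n_permutations permutations for preferred-association tests.
#' @param n_bootstrap bootstrap replicates for uncertainty intervals.
#' @param alpha significance level.
#' @param rng_seed integer seed for all stochastic stages.
#' @return a `study_config` list.
#' @export
study_config <- function(window_days = 31L, shift_days = 31L, clan_cutoff = 0.05,
                         n_permutations = 10000L, n_bootstrap = 100L,
                         alpha = 0.05, rng_seed = 1L) {
  cfg <- list(
    window_days = as.integer(window_days), shift_days = as.integer(shift_days),
    clan_cutoff = clan_cutoff, n_permutations = as.integer(n_permutations),
    n_bootstrap = as.integer(n_bootstrap), alpha = alpha,
    rng_seed = as.integer(rng_seed)
  )
  counts <- c("window_days", "shift_days", "n_permutations", "n_bootstrap")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L) {
      stop("`", nm, "` must be a positive integer", call. = FALSE)
    }
  }
  if (!(cfg$clan_cutoff > 0 && cfg$clan_cutoff < 1)) {
    stop("`clan_cutoff` must lie in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "study_config")
}

#' @rdname study_config
#' @param path file path of a flat key/value YAML config.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(study_config, vals[intersect(names(vals), names(formals(study_config)))])
}

#' @rdname study_config
#' @param config a `study_config` object.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
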