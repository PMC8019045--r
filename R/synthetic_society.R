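# Synthetic multi-level-society generator.
#
# Emulates the field sampling design — one focal unit per day in round-robin,
# scans every 2 h from 07:00 (5 per day), units organised in clans — with a
# known generative model for pairwise association: for every scan with focal
# i, each other unit j is recorded in association independently with
#
#   p_ij = logistic(beta0 + beta_clan * [same clan]
#                   + beta_fruit * z(fruit month) + beta_bond * bond(i,j,t)),
#
# where bond(i,j,t) = 2^(-days since dispersal / halflife) for dyads linked
# by a dispersal event and 0 otherwise. Ecology is a seasonal sinusoid (two
# rainy seasons per year by default) plus noise, clipped at zero.

#' Society configuration
#'
#' Ground-truth parameters of the synthetic society. Default effect sizes are
#' design choices, not field estimates: `beta0 = -4` puts baseline
#' (between-clan) association low enough that clans separate at the 0.05 AI
#' cutoff, `beta_clan = 2.5` gives within-clan indices near 0.1, and
#' `beta_bond = 5` with a 45-day half-life produces a post-dispersal dyadic
#' elevation that decays into the sampling noise by the third month.
#'
#' @param n_clans number of clans.
#' @param units_per_clan integer vector, one entry per clan.
#' @param study_start first study day.
#' @param study_days calendar length of the study, days.
#' @param scans_per_day scans per focal day, 2 h apart from 07:00.
#' @param obs_days_per_month number of observation days per calendar month,
#'   spread evenly through the month (`NULL` = every day). Field studies
#'   rarely sample daily — the study this emulates followed focals on 243 of
#'   624 days, about 12 days per month — and the sampling intensity controls
#'   how precise monthly association indices are.
#' @param beta0 baseline log-odds of association.
#' @param beta_clan same-clan effect (log-odds).
#' @param beta_fruit effect of standardized monthly fruit availability.
#' @param beta_bond post-dispersal dyad effect at the moment of transfer.
#' @param bond_halflife_days half-life of the bond decay, days.
#' @param dispersal_rate baseline expected male transfers per month.
#' @param dispersal_fruit_coef log-linear effect of standardized fruit on the
#'   monthly transfer rate.
#' @param rng_seed integer seed.
#' @return a `society_config` list; unit identifiers are `"U01"`, `"U02"`,
#'   ... assigned clan-by-clan.
#' @export
society_config <- function(n_clans = 2, units_per_clan = c(6, 6),
                           study_start = as.Date("2017-08-28"), study_days = 210,
                           scans_per_day = 5, obs_days_per_month = NULL,
                           beta0 = -4, beta_clan = 2.5,
                           beta_fruit = 0.5, beta_bond = 5,
                           bond_halflife_days = 45, dispersal_rate = 0.3,
                           dispersal_fruit_coef = 1.5, rng_seed = 1L) {
  if (length(units_per_clan) != n_clans) {
    stop("`units_per_clan` must have one entry per clan", call. = FALSE)
  }
  if (bond_halflife_days <= 0) stop("`bond_halflife_days` must be positive", call. = FALSE)
  if (dispersal_rate < 0) stop("`dispersal_rate` must be non-negative", call. = FALSE)
  n_units <- sum(units_per_clan)
  units <- sprintf("U%02d", seq_len(n_units))
  clans <- rep(paste0("clan", seq_len(n_clans)), units_per_clan)
  structure(
    list(
      n_clans = n_clans, units_per_clan = units_per_clan, units = units,
      clans = stats::setNames(clans, units),
      study_start = as.Date(study_start), study_days = as.integer(study_days),
      scans_per_day = as.integer(scans_per_day),
      obs_days_per_month = if (is.null(obs_days_per_month)) NULL else
        as.integer(obs_days_per_month),
      beta0 = beta0, beta_clan = beta_clan, beta_fruit = beta_fruit,
      beta_bond = beta_bond, bond_halflife_days = bond_halflife_days,
      dispersal_rate = dispersal_rate,
      dispersal_fruit_coef = dispersal_fruit_coef,
      rng_seed = as.integer(rng_seed)
    ),
    class = "society_config"
  )
}

#' Ecology configuration
#'
#' Seasonal forcing for the monthly fruit, young-leaf and rainfall series: a
#' sinusoid with `peaks_per_year` maxima (two, matching a bimodal rainy
#' season) around each series' mean, plus Gaussian noise, clipped at zero.
#'
#' @param fruit_mean,fruit_amplitude fruit availability level and seasonal swing.
#' @param leaf_mean,leaf_amplitude young-leaf availability level and swing.
#' @param rain_mean,rain_amplitude monthly rainfall (mm) level and swing.
#' @param peaks_per_year seasonal peaks per 12 months.
#' @param noise_sd Gaussian noise SD applied to every series (on its own scale).
#' @param fruit_lag_months phase lag of the fruit peak behind the rain peak.
#' @return an `ecology_config` list.
#' @export
ecology_config <- function(fruit_mean = 100, fruit_amplitude = 60,
                           leaf_mean = 200, leaf_amplitude = 50,
                           rain_mean = 65, rain_amplitude = 45,
                           peaks_per_year = 2, noise_sd = 0.1,
                           fruit_lag_months = 1) {
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(
    list(fruit_mean = fruit_mean, fruit_amplitude = fruit_amplitude,
         leaf_mean = leaf_mean, leaf_amplitude = leaf_amplitude,
         rain_mean = rain_mean, rain_amplitude = rain_amplitude,
         peaks_per_year = as.integer(peaks_per_year), noise_sd = noise_sd,
         fruit_lag_months = fruit_lag_months),
    class = "ecology_config"
  )
}

#' Named society presets
#'
#' * `"nabugabo-like"`: 13 units — two clans of six plus a singleton
#'   all-male-unit clan — spanning 2017-08-28 to 2019-05-13 (the 21-month
#'   field span) with 12 observation days per month; the scale of the field
#'   study.
#' * `"strong-clan"`: two well-separated clans of six, 180 days.
#' * `"null"`: no clan, fruit or bond effects (all betas except the baseline
#'   are zero), 8 units, 60 days; for type-I calibration.
#' * `"bond"`: one homogeneous clan of ten observed 12 days/month with a
#'   strong dispersal bond (`beta_bond = 4`, 45-day half-life), 160 days;
#'   reproduces the magnitudes seen after real transfers (dyad AI near 0.5
#'   in the first post-dispersal month against baselines near 0.08).
#' * `"no-bond"`: as `"bond"` but `beta_bond = 0`.
#' * `"strong-fruit"`: strong fruit effect on association (`beta_fruit = 1`).
#'
#' @param name preset name.
#' @param rng_seed integer seed stored in the config.
#' @return a `society_config`.
#' @export
society_preset <- function(name = c("nabugabo-like", "strong-clan", "null",
                                    "bond", "no-bond", "strong-fruit"),
                           rng_seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "nabugabo-like" = society_config(
      n_clans = 3, units_per_clan = c(6, 6, 1), study_days = 624,
      obs_days_per_month = 12, rng_seed = rng_seed
    ),
    "strong-clan" = society_config(
      n_clans = 2, units_per_clan = c(6, 6), study_days = 180,
      rng_seed = rng_seed
    ),
    "null" = society_config(
      n_clans = 1, units_per_clan = 8, study_days = 60, beta0 = -2,
      beta_clan = 0, beta_fruit = 0, beta_bond = 0, dispersal_rate = 0,
      rng_seed = rng_seed
    ),
    "bond" = society_config(
      n_clans = 1, units_per_clan = 10, study_days = 160, beta0 = -2.5,
      beta_clan = 0, beta_fruit = 0, beta_bond = 4, bond_halflife_days = 45,
      obs_days_per_month = 12, dispersal_rate = 0, rng_seed = rng_seed
    ),
    "no-bond" = society_config(
      n_clans = 1, units_per_clan = 10, study_days = 160, beta0 = -2.5,
      beta_clan = 0, beta_fruit = 0, beta_bond = 0, obs_days_per_month = 12,
      dispersal_rate = 0, rng_seed = rng_seed
    ),
    "strong-fruit" = society_config(
      n_clans = 2, units_per_clan = c(6, 6), study_days = 365, beta_fruit = 1,
      rng_seed = rng_seed
    )
  )
}

#' Simulate monthly ecology series
#'
#' @param ecology an `ecology_config`.
#' @param months character `"YYYY-MM"` months.
#' @return tibble `month`, `fruit`, `young_leaf`, `rainfall_mm`; all series
#'   non-negative. Uses the current RNG state; seed with `set.seed()`.
#' @export
simulate_ecology <- function(ecology, months) {
  if (!length(months)) stop("need at least one month", call. = FALSE)
  t <- seq_along(months) - 1
  phase <- 2 * pi * ecology$peaks_per_year / 12
  wave <- function(mean, amp, lag = 0) {
    pmax(0, mean + amp * cos(phase * (t - lag)) +
           stats::rnorm(length(t), 0, ecology$noise_sd * max(mean, 1)))
  }
  tibble::tibble(
    month = as.character(months),
    fruit = wave(ecology$fruit_mean, ecology$fruit_amplitude,
                 ecology$fruit_lag_months),
    young_leaf = wave(ecology$leaf_mean, ecology$leaf_amplitude),
    rainfall_mm = wave(ecology$rain_mean, ecology$rain_amplitude)
  )
}

study_months <- function(society) {
  month_seq(society$study_start,
            society$study_start + society$study_days - 1L)
}

#' Simulate focal-follow scans
#'
#' One focal unit per day in round-robin over the roster; `scans_per_day`
#' scans at 2 h spacing from 07:00. Each non-focal unit enters the focal's
#' associate set by an independent Bernoulli draw from the logistic model
#' described in [society_config()].
#'
#' @param society a `society_config`.
#' @param fruit tibble `month`, `fruit` covering the study months (e.g. from
#'   [simulate_ecology()]); standardized internally. `NULL` drops the fruit
#'   term.
#' @param dispersals optional dispersal tibble (see [read_dispersals()]);
#'   dyads linked by a dispersal get the decaying bond effect from
#'   `first_seen_destination` onwards.
#' @return a scan tibble. Uses the current RNG state; seed with `set.seed()`.
#' @export
simulate_scans <- function(society, fruit = NULL, dispersals = NULL) {
  units <- society$units
  n_units <- length(units)
  days <- society$study_start + seq_len(society$study_days) - 1L
  days <- observed_days(days, society$obs_days_per_month)
  focal <- units[((seq_along(days) - 1L) %% n_units) + 1L]
  times <- sprintf("%02d:00", 7 + 2 * (seq_len(society$scans_per_day) - 1))

  z_fruit <- rep(0, length(days))
  if (!is.null(fruit)) {
    z <- stats::setNames(z_pop(fruit$fruit), fruit$month)
    z[is.na(z)] <- 0
    z_fruit <- unname(z[date_month(days)])
  }

  bond_pairs <- bond_pair_table(dispersals)

  n_rows <- length(days) * society$scans_per_day
  day_idx <- rep(seq_along(days), each = society$scans_per_day)
  # linear predictor per (scan row, other unit)
  same_clan <- outer(society$clans, society$clans, "==")
  eta_base <- society$beta0 + society$beta_clan * same_clan[focal[day_idx], , drop = FALSE]
  eta <- eta_base + society$beta_fruit * z_fruit[day_idx]
  if (nrow(bond_pairs)) {
    for (k in seq_len(nrow(bond_pairs))) {
      i <- bond_pairs$a[k]; j <- bond_pairs$b[k]
      delta <- as.numeric(days[day_idx] - bond_pairs$date[k])
      bond <- ifelse(delta >= 0, 2^(-delta / society$bond_halflife_days), 0)
      hit_i <- focal[day_idx] == i
      hit_j <- focal[day_idx] == j
      eta[hit_i, j] <- eta[hit_i, j] + society$beta_bond * bond[hit_i]
      eta[hit_j, i] <- eta[hit_j, i] + society$beta_bond * bond[hit_j]
    }
  }
  p <- stats::plogis(eta)
  draws <- matrix(stats::runif(length(p)) < p, nrow(p), ncol(p))
  colnames(draws) <- units
  # the focal is not its own associate
  draws[cbind(seq_len(n_rows), match(focal[day_idx], units))] <- FALSE

  scan_table(
    date = days[day_idx],
    time = rep(times, length(days)),
    focal_unit = focal[day_idx],
    associates = apply(draws, 1, function(r) units[r], simplify = FALSE)
  )
}

# evenly spaced observation days within each calendar month
observed_days <- function(days, k) {
  if (is.null(k)) return(days)
  keep <- unlist(lapply(split(days, date_month(days)), function(d) {
    if (length(d) <= k) return(d)
    d[unique(round(seq(1, length(d), length.out = k)))]
  }), use.names = FALSE)
  sort(as.Date(keep, origin = "1970-01-01"))
}

bond_pair_table <- function(dispersals) {
  if (is.null(dispersals) || !nrow(dispersals)) {
    return(tibble::tibble(a = character(), b = character(), date = as.Date(character())))
  }
  key <- paste(dispersals$from_unit, dispersals$to_unit,
               dispersals$first_seen_destination)
  d <- dispersals[!duplicated(key), ]
  tibble::tibble(a = d$from_unit, b = d$to_unit, date = d$first_seen_destination)
}

#' Simulate male dispersal events
#'
#' Monthly transfer counts are Poisson with expectation
#' `dispersal_rate * exp(dispersal_fruit_coef * z(fruit))`; each transfer
#' picks an ordered origin/destination pair uniformly over distinct units
#' and a date range of at most 14 days inside the month.
#'
#' @inheritParams simulate_scans
#' @return a dispersal tibble (one row per dispersing male). Uses the
#'   current RNG state.
#' @export
simulate_dispersals <- function(society, fruit = NULL) {
  if (length(society$units) < 2) stop("need at least 2 units", call. = FALSE)
  months <- study_months(society)
  z <- rep(0, length(months))
  if (!is.null(fruit)) {
    zz <- stats::setNames(z_pop(fruit$fruit), fruit$month)
    zz[is.na(zz)] <- 0
    z <- unname(zz[months])
  }
  lambda <- society$dispersal_rate * exp(society$dispersal_fruit_coef * z)
  counts <- stats::rpois(length(months), lambda)
  rows <- list()
  id <- 0L
  for (m in seq_along(months)) {
    for (k in seq_len(counts[m])) {
      id <- id + 1L
      pair <- sample(society$units, 2)
      first <- month_first_day(months[m])
      ndays <- days_in_month(months[m])
      span <- sample.int(14, 1) - 1L
      start_day <- sample.int(max(1L, ndays - span), 1)
      last_seen <- first + start_day - 1L
      rows[[id]] <- tibble::tibble(
        individual_id = sprintf("M%03d", id), sex = "male",
        from_unit = pair[1], to_unit = pair[2],
        last_seen_origin = last_seen,
        first_seen_destination = last_seen + span
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(
      individual_id = character(), sex = character(), from_unit = character(),
      to_unit = character(), last_seen_origin = as.Date(character()),
      first_seen_destination = as.Date(character())
    ))
  }
  dplyr::bind_rows(rows)
}

#' Generate a complete synthetic dataset on disk
#'
#' Simulates ecology, dispersals and scans under one seed and writes the
#' full set of study inputs — `scans.csv`, `phenology.csv`, `basal_area.csv`,
#' `rainfall.csv`, `dispersals.csv` — plus `ground_truth.json` recording the
#' clan partition, every generative parameter, the dispersal list and the
#' seed. The phenology/basal-area pair is constructed so that the fruit and
#' young-leaf food availability indices recompute exactly to the simulated
#' monthly series (one synthetic tree species with basal area 1; monthly
#' scores are written as the series rescaled to 0-4, with the scale factor
#' recorded in the sidecar).
#'
#' @param society a `society_config`.
#' @param ecology an `ecology_config`.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the generated tibbles and ground truth.
#' @export
generate_dataset <- function(society, ecology = ecology_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(society$rng_seed)
  months <- study_months(society)
  eco <- simulate_ecology(ecology, months)
  dispersals <- simulate_dispersals(society, fruit = eco[, c("month", "fruit")])
  scans <- simulate_scans(society, fruit = eco[, c("month", "fruit")],
                          dispersals = dispersals)

  # phenology/basal-area pair whose FAI reproduces the simulated series
  fruit_scale <- max(eco$fruit, 1e-9) / 4
  leaf_scale <- max(eco$young_leaf, 1e-9) / 4
  phenology <- dplyr::bind_rows(
    tibble::tibble(tree_id = "synthfruit-1", species = "synthfruit",
                   month = eco$month, plant_part = "ripe_fruit",
                   score = as.integer(round(eco$fruit / fruit_scale))),
    tibble::tibble(tree_id = "synthleaf-1", species = "synthleaf",
                   month = eco$month, plant_part = "young_leaf",
                   score = as.integer(round(eco$young_leaf / leaf_scale)))
  )
  basal <- tibble::tibble(species = c("synthfruit", "synthleaf"),
                          basal_area_m2 = c(1, 1))
  rainfall <- tibble::tibble(month = eco$month, rainfall_mm = eco$rainfall_mm)

  write_scans(scans, file.path(dir, "scans.csv"))
  write_phenology(phenology, file.path(dir, "phenology.csv"))
  write_basal_areas(basal, file.path(dir, "basal_area.csv"))
  write_rainfall(rainfall, file.path(dir, "rainfall.csv"))
  write_dispersals(dispersals, file.path(dir, "dispersals.csv"))

  truth <- list(
    clans = as.list(society$clans),
    betas = list(beta0 = society$beta0, beta_clan = society$beta_clan,
                 beta_fruit = society$beta_fruit, beta_bond = society$beta_bond,
                 bond_halflife_days = society$bond_halflife_days),
    dispersal = list(rate = society$dispersal_rate,
                     fruit_coef = society$dispersal_fruit_coef,
                     events = nrow(dispersals)),
    ecology = list(fruit_score_scale = fruit_scale, leaf_score_scale = leaf_scale),
    seed = society$rng_seed
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scans = scans, ecology = eco, phenology = phenology,
                 basal_areas = basal, rainfall = rainfall,
                 dispersals = dispersals, ground_truth = truth))
}
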