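# Permutation tests for preferred/avoided association and data-stream null
# bands for chance-encounter network density.
#
# Two null schemes are provided. "data_stream" randomizes the observation
# stream itself by sequential pairwise swaps of associates between scans,
# preserving every scan's group size and every unit's sighting count (the
# classic group-membership randomization for association data). "node_label"
# permutes each unit's presence pattern across scans independently,
# preserving sighting counts but not group sizes; it is the cheaper
# node-level null. A high coefficient of variation of the dyadic AIs
# relative to either null indicates preferred/avoided companionships, so the
# test is right-tailed.

#' Coefficient of variation of dyadic association indices
#'
#' Population SD over mean of the defined off-diagonal dyads (each dyad
#' counted once). `sd = "sample"` switches to the n-1 denominator.
#'
#' @param x an `assoc_matrix`.
#' @param sd `"population"` (default) or `"sample"`.
#' @return CV, a non-negative real.
#' @export
cv_statistic <- function(x, sd = c("population", "sample")) {
  sd <- match.arg(sd)
  up <- upper.tri(x$ai)
  vals <- x$ai[up & x$defined]
  if (length(vals) < 3) stop("need at least 3 defined dyads", call. = FALSE)
  mu <- mean(vals)
  if (mu == 0) stop("mean AI is zero: CV undefined", call. = FALSE)
  s <- if (sd == "population") sqrt(mean((vals - mu)^2)) else stats::sd(vals)
  s / mu
}

# scan tibble -> list(presence 0/1 matrix, focal col index per scan, day id)
stream_state <- function(scans, units = NULL) {
  m <- presence_matrix(scans, units = units)
  storage.mode(m) <- "integer"
  list(
    x = m,
    focal = match(scans$focal_unit, colnames(m)) - 1L,
    day = as.integer(as.factor(as.character(scans$date)))
  )
}

# population CV of the defined dyadic AIs straight from a presence matrix
cv_from_presence <- function(m) {
  storage.mode(m) <- "double"
  joint <- crossprod(m)
  n_ind <- diag(joint)
  den <- outer(n_ind, n_ind, "+") - joint
  up <- upper.tri(den)
  ok <- up & den > 0
  vals <- joint[ok] / den[ok]
  mu <- mean(vals)
  sqrt(mean((vals - mu)^2)) / mu
}

#' Data-stream permutations of a scan set
#'
#' Runs the sequential swap chain and emits one permuted presence matrix
#' every `swaps_per_sample` accepted swaps, after `burn_in` accepted swaps of
#' burn-in. Each emitted state has exactly the observed group sizes and
#' per-unit sighting counts. If the chain cannot find legal swaps (for
#' example, all scans identical) a warning reports the shortfall.
#'
#' @param scans scan tibble.
#' @param n_permutations number of permuted datasets to emit.
#' @param swaps_per_sample accepted swaps between successive samples
#'   (default 500: at shorter thinning successive samples are visibly
#'   autocorrelated and the permutation p-values become anticonservative).
#' @param constraint `"none"` (default) or `"day"` (swap only within the
#'   same calendar day). Under a one-focal-unit-per-day design, day-constrained
#'   swaps can only rearrange associates among scans that share a focal, which
#'   nearly preserves the observed focal-associate joint counts and leaves the
#'   test with almost no power; the unconstrained chain is the usable null for
#'   such data and is therefore the default.
#' @param burn_in accepted swaps before the first sample.
#' @param units roster.
#' @param seed optional integer seed.
#' @return list of 0/1 presence matrices (scans x units).
#' @export
data_stream_permute <- function(scans, n_permutations, swaps_per_sample = 500,
                                constraint = c("none", "day"), burn_in = 2000,
                                units = NULL, seed = NULL) {
  constraint <- match.arg(constraint)
  if (!is.null(seed)) set.seed(seed)
  st <- stream_state(scans, units)
  x <- st$x + 0L  # private copy: cpp_stream_swaps mutates in place
  same_day <- constraint == "day"
  budget_factor <- 2000
  got <- cpp_stream_swaps(x, st$focal, st$day, as.integer(burn_in), same_day,
                          budget_factor * burn_in + 1e5)
  short <- 0L
  out <- vector("list", n_permutations)
  for (k in seq_len(n_permutations)) {
    acc <- cpp_stream_swaps(x, st$focal, st$day, as.integer(swaps_per_sample),
                            same_day, budget_factor * swaps_per_sample + 1e5)
    if (acc < swaps_per_sample) short <- short + 1L
    out[[k]] <- x + 0L
  }
  if (got < burn_in || short > 0) {
    warning(sprintf(
      "swap chain mixing is limited: burn-in %d/%d, %d/%d samples short of %d swaps",
      got, burn_in, short, n_permutations, swaps_per_sample), call. = FALSE)
  }
  out
}

# node-label null: permute each unit's presence across scans independently,
# keeping focal placements fixed (a unit is never absent from its own follow)
node_label_permute <- function(state) {
  x <- state$x
  n <- nrow(x)
  for (u in seq_len(ncol(x))) {
    is_focal <- state$focal == (u - 1L)
    free <- which(!is_focal)
    x[free, u] <- x[free, u][sample.int(length(free))]
  }
  x
}

#' Permutation test for preferred/avoided association
#'
#' Right-tailed test of the observed CV of dyadic association indices
#' against its permutation distribution, with the add-one estimator
#' `p = (k + 1) / (n + 1)` where `k` counts permutations with CV at least
#' the observed value.
#'
#' @param scans scan tibble.
#' @param scheme `"data_stream"` (default) or `"node_label"`.
#' @param n_permutations number of permutations (default 10,000; fewer than
#'   100 triggers an instability warning).
#' @param seed optional integer seed.
#' @param units roster.
#' @param ... passed to [data_stream_permute()] (`swaps_per_sample`,
#'   `constraint`, `burn_in`).
#' @return a `perm_test` list: `cv_obs`, `cv_rand_mean`, `p_value`,
#'   `n_permutations`, `scheme`, `seed`.
#' @export
preferred_association_test <- function(scans, scheme = c("data_stream", "node_label"),
                                       n_permutations = 10000, seed = NULL,
                                       units = NULL, ...) {
  scheme <- match.arg(scheme)
  if (n_permutations < 100) {
    warning("fewer than 100 permutations: p-value will be unstable", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  st <- stream_state(scans, units)
  cv_obs <- cv_statistic(ai_from_presence(st$x > 0L))
  cv_rand <- if (scheme == "data_stream") {
    args <- list(...)
    sps <- args$swaps_per_sample %||% 500
    burn_in <- args$burn_in %||% 2000
    same_day <- identical(args$constraint, "day")
    x <- st$x + 0L
    budget <- 2000 * max(burn_in, sps) + 1e5
    short <- cpp_stream_swaps(x, st$focal, st$day, as.integer(burn_in),
                              same_day, budget) < burn_in
    out <- vapply(seq_len(n_permutations), function(k) {
      acc <- cpp_stream_swaps(x, st$focal, st$day, as.integer(sps), same_day, budget)
      short <<- short || acc < sps
      cv_from_presence(x)
    }, 1)
    if (short) warning("swap chain mixing is limited", call. = FALSE)
    out
  } else {
    vapply(seq_len(n_permutations), function(k) {
      cv_statistic(ai_from_presence(node_label_permute(st) > 0L))
    }, 1)
  }
  k <- sum(cv_rand >= cv_obs)
  structure(
    list(cv_obs = cv_obs, cv_rand_mean = mean(cv_rand),
         p_value = (k + 1) / (n_permutations + 1),
         n_permutations = as.integer(n_permutations), scheme = scheme,
         seed = seed),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "Preferred-association permutation test (%s, %d permutations)\n  CV_obs = %.3f, CV_rand = %.3f, p = %.4g\n",
    x$scheme, x$n_permutations, x$cv_obs, x$cv_rand_mean, x$p_value))
  invisible(x)
}

#' @rdname tidy.assoc_matrix
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(cv_obs = x$cv_obs, cv_rand_mean = x$cv_rand_mean,
                 p_value = x$p_value, n_permutations = x$n_permutations,
                 scheme = x$scheme)
}

#' Write a permutation-test result as JSON
#'
#' @param x a `perm_test`.
#' @param path output path.
#' @export
write_perm_test <- function(x, path) {
  jsonlite::write_json(
    list(cv_obs = x$cv_obs, cv_rand_mean = x$cv_rand_mean,
         p_value = x$p_value, n_permutations = x$n_permutations,
         scheme = x$scheme, seed = x$seed),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Chance-encounter null band for per-window edge density
#'
#' For each window of a network series, data-stream permutations of that
#' window's scans give the 2.5th-97.5th percentile band of edge density
#' expected from chance encounters given group sizes and sighting counts.
#' Windows with fewer than 2 scans get an undefined (`NA`) band.
#'
#' @param scans full scan tibble.
#' @param series a `network_series` defining the windows.
#' @param n_permutations permutations per window.
#' @param seed optional integer seed.
#' @param level band mass (default 0.95).
#' @param ... passed to [data_stream_permute()].
#' @return tibble `window_start`, `window_end`, `observed`, `lower`, `upper`.
#' @export
null_density_band <- function(scans, series, n_permutations = 1000, seed = NULL,
                              level = 0.95, ...) {
  if (!is.null(seed)) set.seed(seed)
  units <- attr(series, "units")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  n_dyads <- choose(length(units), 2)
  rows <- lapply(seq_len(nrow(series)), function(i) {
    sc <- scans[scans$date >= series$window_start[i] &
                  scans$date <= series$window_end[i], ]
    obs <- edge_density(series$snapshot[[i]])
    if (nrow(sc) < 2) {
      return(tibble::tibble(window_start = series$window_start[i],
                            window_end = series$window_end[i],
                            observed = obs, lower = NA_real_, upper = NA_real_))
    }
    mats <- data_stream_permute(sc, n_permutations, units = units, ...)
    dens <- vapply(mats, function(m) {
      am <- ai_from_presence(m > 0L)
      sum(am$ai[upper.tri(am$ai)] > 0) / n_dyads
    }, 1)
    q <- stats::quantile(dens, probs, names = FALSE, type = 7)
    tibble::tibble(window_start = series$window_start[i],
                   window_end = series$window_end[i],
                   observed = obs, lower = q[1], upper = q[2])
  })
  dplyr::bind_rows(rows)
}

#' @rdname null_density_band
#' @param band tibble from `null_density_band()`.
#' @param path output CSV path.
#' @export
write_density_band <- function(band, path) {
  utils::write.csv(as.data.frame(band), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
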