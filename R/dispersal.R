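# Dispersal timing and its dyadic after-effects.
#
# Each dispersal is dated by a last-seen/first-seen range; the event month is
# the calendar month holding the most days of that range (ties toward the
# earlier month). Monthly male transfer counts are correlated with ecology by
# Monte-Carlo Spearman tests (robust to the many tied zero months), and the
# origin-destination dyad's association in the 1-3 months after a transfer is
# compared against the units' baseline associations with third units by
# one-sided exact Wilcoxon signed-rank tests.

#' Assign a dispersal event to a calendar month
#'
#' The month containing the greatest number of days of
#' `[last_seen_origin, first_seen_destination]`; ties resolve to the earlier
#' month.
#'
#' @param last_seen_origin,first_seen_destination `Date` scalars or vectors
#'   (vectorized over events).
#' @return `"YYYY-MM"` month(s).
#' @export
assign_dispersal_month <- function(last_seen_origin, first_seen_destination) {
  mapply(function(from, to) {
    from <- as.Date(from); to <- as.Date(to)
    if (from > to) stop("date-range inversion", call. = FALSE)
    days <- seq(from, to, by = "day")
    counts <- table(date_month(days))
    names(counts)[which.max(counts)]  # first max = earlier month
  }, last_seen_origin, first_seen_destination, USE.NAMES = FALSE)
}

#' Monthly male transfer counts
#'
#' One count per dispersing male (a parallel transfer of k males adds k to
#' its month); females are excluded; months without transfers are zero.
#'
#' @param events dispersal tibble (see [read_dispersals()]).
#' @param span length-2 `Date` or `"YYYY-MM"` giving the study span.
#' @return tibble `month`, `male_transfers` over the contiguous span months.
#' @export
monthly_transfer_counts <- function(events, span) {
  months <- month_seq(span[1], span[2])
  out <- tibble::tibble(month = months, male_transfers = 0L)
  males <- events[events$sex == "male", ]
  if (nrow(males)) {
    m <- assign_dispersal_month(males$last_seen_origin,
                                males$first_seen_destination)
    tab <- table(factor(m, levels = months))
    out$male_transfers <- as.integer(tab)
  }
  out
}

#' @rdname monthly_transfer_counts
#' @param counts transfer-count tibble.
#' @param path output CSV path.
#' @export
write_transfer_counts <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Monte-Carlo Spearman rank correlation
#'
#' Spearman's rho on mid-ranks with a two-sided Monte-Carlo p-value: the
#' add-one proportion of random permutations of `y` whose |rho| reaches the
#' observed |rho|. Preferred over the asymptotic test when the series carry
#' many ties (months with zero transfers).
#'
#' @param x,y equal-length numeric series (length >= 5).
#' @param n_mc number of Monte-Carlo permutations (default 10,000).
#' @param seed optional integer seed.
#' @return tibble `rho`, `p_value`, `n`, `n_mc`.
#' @export
spearman_mc <- function(x, y, n_mc = 10000, seed = NULL) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (length(x) < 5) stop("need at least 5 paired observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in a series: rho undefined", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rx <- rank(x)
  ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  hits <- sum(vapply(seq_len(n_mc), function(k) {
    abs(stats::cor(rx, sample(ry))) >= abs(rho_obs) - 1e-12
  }, TRUE))
  tibble::tibble(rho = rho_obs, p_value = (hits + 1) / (n_mc + 1),
                 n = length(x), n_mc = as.integer(n_mc))
}

#' Bonferroni-corrected significance level
#'
#' @param alpha family-wise level (default 0.05).
#' @param m number of comparisons (default 3: fruit, young leaves, rainfall).
#' @return list with `alpha` (exact, `alpha/m`) and `display` (rounded to 3
#'   decimals, the conventional reported form).
#' @export
bonferroni <- function(alpha = 0.05, m = 3) {
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  corrected <- alpha / m
  list(alpha = corrected, display = round(corrected, 3))
}

# scans of one calendar month
month_scans <- function(scans, month) {
  scans[date_month(scans$date) == month, ]
}

#' Post-dispersal dyad association
#'
#' Simple AI between the origin and destination units over the scans of the
#' calendar month `assigned_month + month_offset`. `NA` (flagged missing) if
#' that month has no scans.
#'
#' @param event one-row dispersal tibble.
#' @param scans full scan tibble.
#' @param month_offset months after the assigned dispersal month (1-3).
#' @return AI in `[0, 1]`, or `NA`.
#' @export
post_dispersal_dyad_ai <- function(event, scans, month_offset) {
  m0 <- assign_dispersal_month(event$last_seen_origin,
                               event$first_seen_destination)
  sc <- month_scans(scans, month_shift(m0, month_offset))
  if (!nrow(sc)) return(NA_real_)
  simple_ai(dyad_counts(sc, event$from_unit, event$to_unit))
}

#' Baseline associations of the units involved in a dispersal
#'
#' Control set: every third unit that the origin or destination unit
#' associated with (AI > 0) during the transfer month, the dyad of interest
#' excluded. The returned values are those control dyads' AIs in the
#' evaluation month (`assigned_month + month_offset`; offset 0 = the
#' transfer month itself), pooled over the two focal units.
#'
#' @inheritParams post_dispersal_dyad_ai
#' @param month_offset evaluation month relative to the transfer month.
#' @return numeric vector of baseline AIs (possibly empty).
#' @export
baseline_ais <- function(event, scans, month_offset = 0) {
  m0 <- assign_dispersal_month(event$last_seen_origin,
                               event$first_seen_destination)
  sc0 <- month_scans(scans, m0)
  if (!nrow(sc0)) return(numeric(0))
  am0 <- association_matrix(sc0)
  sc_eval <- if (month_offset == 0) sc0 else {
    month_scans(scans, month_shift(m0, month_offset))
  }
  if (!nrow(sc_eval)) return(numeric(0))
  vals <- c()
  for (u in c(event$from_unit, event$to_unit)) {
    if (!u %in% am0$units) next
    partners <- am0$units[am0$ai[u, ] > 0 & !is.na(am0$ai[u, ])]
    partners <- setdiff(partners, c(event$from_unit, event$to_unit))
    for (v in partners) {
      vals <- c(vals, simple_ai(dyad_counts(sc_eval, u, v)))
    }
  }
  vals[!is.na(vals)]
}

#' Exact one-sample Wilcoxon signed-rank test
#'
#' One-sided test that the baseline values lie below the dyad value: signed
#' ranks of `dyad_ai - baseline_ais`, zeros dropped, ties mid-ranked; exact
#' enumeration of all sign assignments for n <= 15, normal approximation
#' with tie correction above.
#'
#' @param baseline_ais numeric control values.
#' @param dyad_ai the focal dyad's value.
#' @return one-sided p-value for H1: baselines < dyad value.
#' @export
wilcoxon_one_sample <- function(baseline_ais, dyad_ai) {
  d <- dyad_ai - baseline_ais
  d <- d[d != 0]
  n <- length(d)
  if (n < 3) stop("need at least 3 non-zero differences", call. = FALSE)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  if (n <= 15) {
    # exact: all 2^n sign assignments of the observed |d| ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- drop(signs %*% r)
    mean(w_all >= w_obs - 1e-12)
  } else {
    mu <- sum(r) / 2
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    stats::pnorm((w_obs - mu - 0.5) / sqrt(sig2), lower.tail = FALSE)
  }
}

#' Post-dispersal association analysis
#'
#' For every dispersal event (several males moving between the same pair of
#' units in the same month count once) and every offset month 1-3, compares
#' the origin-destination dyad's AI against the baseline AIs of the involved
#' units with their transfer-month associates, by a one-sided Wilcoxon
#' signed-rank test. Offsets beyond the data, empty control sets, or too few
#' non-zero differences are flagged missing (`NA` p) rather than dropped.
#'
#' @param events dispersal tibble.
#' @param scans full scan tibble.
#' @param alpha significance level for the `significant` flag.
#' @return tibble `event_id`, `from_unit`, `to_unit`, `event_month`,
#'   `offset`, `dyad_ai`, `baseline_n`, `baseline_mean`, `p_value`,
#'   `significant`.
#' @export
post_dispersal_analysis <- function(events, scans, alpha = 0.05) {
  if (!nrow(events)) {
    return(tibble::tibble(
      event_id = character(), from_unit = character(), to_unit = character(),
      event_month = character(), offset = integer(), dyad_ai = numeric(),
      baseline_n = integer(), baseline_mean = numeric(), p_value = numeric(),
      significant = logical()
    ))
  }
  events$..month.. <- assign_dispersal_month(events$last_seen_origin,
                                             events$first_seen_destination)
  key <- paste(events$from_unit, events$to_unit, events$..month..)
  uni <- events[!duplicated(key), ]
  rows <- lapply(seq_len(nrow(uni)), function(i) {
    ev <- uni[i, ]
    out <- lapply(1:3, function(off) {
      dyad <- post_dispersal_dyad_ai(ev, scans, off)
      base <- baseline_ais(ev, scans, month_offset = off)
      p <- NA_real_
      if (!is.na(dyad) && length(base) >= 3) {
        p <- tryCatch(wilcoxon_one_sample(base, dyad), error = function(e) NA_real_)
      }
      tibble::tibble(
        event_id = sprintf("%s-%s-%s", ev$from_unit, ev$to_unit, ev$..month..),
        from_unit = ev$from_unit, to_unit = ev$to_unit,
        event_month = ev$..month.., offset = off, dyad_ai = dyad,
        baseline_n = length(base),
        baseline_mean = if (length(base)) mean(base) else NA_real_,
        p_value = p,
        significant = !is.na(p) & p < alpha
      )
    })
    dplyr::bind_rows(out)
  })
  dplyr::bind_rows(rows)
}

#' @rdname post_dispersal_analysis
#' @param comparisons tibble from `post_dispersal_analysis()`.
#' @param path output CSV path.
#' @export
write_post_dispersal <- function(comparisons, path) {
  utils::write.csv(as.data.frame(comparisons), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
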