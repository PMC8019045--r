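# Time-aggregated weighted networks on a sliding window, node and network
# metrics, cosine-similarity stability, bootstrap intervals, and window-size
# selection.
#
# Edge presence means AI > 0 (no threshold) for degree, density and the
# clustering coefficient; strength sums raw AI weights. A weight threshold
# is available for sensitivity analysis.

#' Build a network snapshot from scans in one window
#'
#' @param scans scan tibble already restricted to the window.
#' @param units roster.
#' @param window length-2 `Date`: `[start, end)` half-open.
#' @return a `network_snapshot`: the window, roster, the `assoc_matrix`, and
#'   a long `edges` tibble of positive-weight dyads.
#' @export
network_snapshot <- function(scans, units, window = NULL) {
  if (nrow(scans)) {
    am <- association_matrix(scans, units = units, period = window)
  } else {
    m <- matrix(FALSE, 0, length(units), dimnames = list(NULL, units))
    am <- ai_from_presence_empty(m, window)
  }
  d <- tidy(am)
  edges <- d[!is.na(d$ai) & d$ai > 0, c("unit_a", "unit_b", "ai")]
  structure(
    list(window = window, units = units, matrix = am, edges = edges,
         n_scans = nrow(scans)),
    class = "network_snapshot"
  )
}

# all-zero association object for an empty window
ai_from_presence_empty <- function(m, period) {
  n <- ncol(m)
  z <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  structure(
    list(units = colnames(m), ai = z + diag(NA_real_, n),
         defined = matrix(FALSE, n, n, dimnames = dimnames(z)),
         joint = z, n_union = z,
         sightings = stats::setNames(numeric(n), colnames(m)),
         n_scans = 0L, period = period, denominator = "union"),
    class = "assoc_matrix"
  )
}

#' @export
print.network_snapshot <- function(x, ...) {
  cat(sprintf("Network snapshot %s to %s: %d units, %d edges, %d scans\n",
              x$window[1], x$window[2] - 1, length(x$units), nrow(x$edges),
              x$n_scans))
  invisible(x)
}

#' Sliding-window network series
#'
#' Splits the scans into consecutive half-open windows
#' `[start, start + window_days)` shifted by `shift_days`, and builds a
#' weighted network per window. Only complete windows are emitted: a
#' trailing stub shorter than `window_days` is dropped.
#'
#' @param scans scan tibble.
#' @param window_days,shift_days window size and shift, days (default 31/31).
#' @param span optional length-2 `Date` (inclusive) fixing the study span;
#'   defaults to the scan date range.
#' @param units roster; defaults to all units in the scans.
#' @return a `network_series` tibble: `window_start`, `window_end`
#'   (inclusive last day), `n_scans`, and a `snapshot` list-column.
#' @export
window_networks <- function(scans, window_days = 31, shift_days = 31,
                            span = NULL, units = NULL) {
  if (is.null(span)) {
    if (!nrow(scans)) stop("no scans and no `span` supplied", call. = FALSE)
    span <- range(scans$date)
  }
  span <- as.Date(span)
  if (is.null(units)) {
    units <- sort(unique(c(scans$focal_unit, unlist(scans$associates))))
  }
  n_days <- as.integer(span[2] - span[1]) + 1L
  if (n_days < window_days) stop("span shorter than one window", call. = FALSE)
  if (!nrow(scans)) warning("empty scan set: snapshots will be empty", call. = FALSE)
  n_win <- (n_days - window_days) %/% shift_days + 1L
  starts <- span[1] + shift_days * (seq_len(n_win) - 1L)
  snaps <- lapply(starts, function(s) {
    w <- c(s, s + window_days)
    network_snapshot(scans[scans$date >= w[1] & scans$date < w[2], ], units, w)
  })
  out <- tibble::tibble(
    window_start = starts,
    window_end = starts + window_days - 1L,
    n_scans = vapply(snaps, function(s) s$n_scans, 1L),
    snapshot = snaps
  )
  attr(out, "window_days") <- window_days
  attr(out, "shift_days") <- shift_days
  attr(out, "units") <- units
  class(out) <- c("network_series", class(out))
  out
}

weight_matrix <- function(snapshot) {
  w <- snapshot$matrix$ai
  diag(w) <- 0
  w
}

snapshot_graph <- function(snapshot, threshold = 0) {
  w <- weight_matrix(snapshot)
  w[w <= threshold] <- 0
  igraph::graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE)
}

#' Node and network metrics of a snapshot
#'
#' Degree counts a node's positive-weight edges; strength sums its edge
#' weights; edge density is realized dyads over possible dyads; the
#' clustering coefficient is the global transitivity (3 x triangles over
#' connected triples) of the binarized graph, undefined (`NA`) when the
#' graph has no connected triple.
#'
#' @param snapshot a `network_snapshot`.
#' @param unit unit identifier.
#' @param threshold edge-presence threshold on AI (default 0: any positive
#'   association is an edge).
#' @export
node_degree <- function(snapshot, unit, threshold = 0) {
  w <- unit_row(snapshot, unit)
  sum(w > threshold)
}

#' @rdname node_degree
#' @export
node_strength <- function(snapshot, unit) {
  sum(unit_row(snapshot, unit))
}

unit_row <- function(snapshot, unit) {
  if (!unit %in% snapshot$units) stop("unknown unit: ", unit, call. = FALSE)
  weight_matrix(snapshot)[unit, ]
}

#' @rdname node_degree
#' @export
edge_density <- function(snapshot, threshold = 0) {
  w <- weight_matrix(snapshot)
  n <- nrow(w)
  if (n < 2) stop("need at least 2 units", call. = FALSE)
  sum(w[upper.tri(w)] > threshold) / choose(n, 2)
}

#' @rdname node_degree
#' @export
clustering_coefficient <- function(snapshot, threshold = 0) {
  w <- weight_matrix(snapshot)
  if (nrow(w) < 3) stop("need at least 3 units", call. = FALSE)
  g <- snapshot_graph(snapshot, threshold)
  cc <- igraph::transitivity(g, type = "global")
  if (is.nan(cc)) NA_real_ else cc
}

#' Cosine similarity of two weighted networks
#'
#' The normalized dot product of the two networks' edge-weight vectors over
#' the union of their dyads: 1 means identical association structure (equal
#' up to overall scale), 0 means no shared associations. If either network
#' has no edges the similarity is 0 by convention.
#'
#' @param net1,net2 `network_snapshot`s (rosters may differ; the union is
#'   used, absent dyads padded with weight 0).
#' @return value in `[0, 1]`.
#' @export
cosine_similarity <- function(net1, net2) {
  units <- sort(union(net1$units, net2$units))
  v1 <- edge_vector(net1, units)
  v2 <- edge_vector(net2, units)
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(0)
  sum(v1 * v2) / (n1 * n2)
}

edge_vector <- function(net, units) {
  w <- matrix(0, length(units), length(units), dimnames = list(units, units))
  wm <- weight_matrix(net)
  w[net$units, net$units] <- wm
  w[upper.tri(w)]
}

#' Network stability series
#'
#' Per-window cosine similarity either to the previous window (`lag1`,
#' short-term variability; the first window is `NA`) or to the first window
#' (`to_first`, long-term variability; the first window maps to 1).
#'
#' @param series a `network_series`.
#' @param mode `"lag1"` or `"to_first"`.
#' @return tibble `window_start`, `cosine`.
#' @export
stability_series <- function(series, mode = c("lag1", "to_first")) {
  mode <- match.arg(mode)
  snaps <- series$snapshot
  if (length(snaps) < 2) stop("need at least 2 snapshots", call. = FALSE)
  cosine <- if (mode == "lag1") {
    c(NA_real_, vapply(seq_along(snaps)[-1], function(i) {
      cosine_similarity(snaps[[i - 1]], snaps[[i]])
    }, 1))
  } else {
    c(1, vapply(seq_along(snaps)[-1], function(i) {
      cosine_similarity(snaps[[1]], snaps[[i]])
    }, 1))
  }
  tibble::tibble(window_start = series$window_start, cosine = cosine)
}

#' Metric table for a network series
#'
#' @param series a `network_series`.
#' @param threshold edge-presence threshold on AI.
#' @return tibble with per-window `density`, `clustering`, `mean_degree`,
#'   `mean_strength`, and per-window per-unit node metrics in
#'   [node_metrics()].
#' @export
network_metrics <- function(series, threshold = 0) {
  rows <- lapply(seq_len(nrow(series)), function(i) {
    s <- series$snapshot[[i]]
    tibble::tibble(
      window_start = series$window_start[i],
      density = edge_density(s, threshold),
      clustering = clustering_coefficient(s, threshold),
      mean_degree = mean(vapply(s$units, node_degree, 1, snapshot = s,
                                threshold = threshold)),
      mean_strength = mean(vapply(s$units, node_strength, 1, snapshot = s))
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname network_metrics
#' @export
node_metrics <- function(series, threshold = 0) {
  rows <- lapply(seq_len(nrow(series)), function(i) {
    s <- series$snapshot[[i]]
    tibble::tibble(
      window_start = series$window_start[i],
      unit = s$units,
      degree = vapply(s$units, node_degree, 1, snapshot = s,
                      threshold = threshold),
      strength = vapply(s$units, node_strength, 1, snapshot = s)
    )
  })
  dplyr::bind_rows(rows)
}

#' Bootstrap interval for a window statistic
#'
#' Resamples the window's scans with replacement (same count), rebuilds the
#' snapshot and recomputes the statistic; returns the 95% highest-density
#' interval (the shortest interval containing the requested mass) over the
#' replicates.
#'
#' @param scans scans in the window.
#' @param statistic function of a `network_snapshot`.
#' @param n_boot replicates (default 100).
#' @param level interval mass (default 0.95).
#' @param units roster.
#' @param seed optional integer seed.
#' @return tibble `lower`, `upper`, `n_boot`, `n_failed`.
#' @export
bootstrap_ci <- function(scans, statistic, n_boot = 100, level = 0.95,
                         units = NULL, seed = NULL) {
  if (nrow(scans) < 2) stop("need at least 2 scans", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(units)) {
    units <- sort(unique(c(scans$focal_unit, unlist(scans$associates))))
  }
  vals <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(scans), nrow(scans), replace = TRUE)
    s <- network_snapshot(scans[idx, ], units)
    out <- tryCatch(statistic(s), error = function(e) NA_real_)
    if (is.null(out)) NA_real_ else out
  }, 1)
  n_failed <- sum(is.na(vals))
  if (n_failed > n_boot / 2) {
    stop("statistic undefined in more than half the bootstrap replicates",
         call. = FALSE)
  }
  hdi <- hdi_interval(vals[!is.na(vals)], level)
  tibble::tibble(lower = hdi[1], upper = hdi[2], n_boot = n_boot,
                 n_failed = n_failed)
}

# shortest interval containing `level` mass of the sample
hdi_interval <- function(x, level = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1L, ceiling(level * n))  # points needed for the requested mass
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths)
  c(x[i], x[i + k - 1])
}

#' Choose a sliding-window size
#'
#' For each candidate size, the signal is the variance of edge density
#' across windows and the noise is the mean within-window bootstrap variance
#' of density; the candidate maximizing signal/noise is chosen (ties and
#' near-noise-free inputs resolve toward the smallest candidate).
#' `criterion = "variance"` instead maximizes raw across-window variance.
#'
#' @param scans scan tibble.
#' @param candidate_days integer candidates (days).
#' @param n_boot bootstrap replicates per window.
#' @param seed optional seed.
#' @param span optional study span.
#' @param criterion `"signal_noise"` (default) or `"variance"`.
#' @return list with `window_days` (chosen) and `diagnostics` tibble
#'   (`window_days`, `n_windows`, `signal`, `noise`, `ratio`).
#' @export
select_window_size <- function(scans, candidate_days, n_boot = 50, seed = NULL,
                               span = NULL, criterion = c("signal_noise", "variance")) {
  criterion <- match.arg(criterion)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(span)) span <- range(scans$date)
  n_days <- as.integer(span[2] - span[1]) + 1L
  if (any(candidate_days > n_days)) {
    stop("candidate window longer than the study span", call. = FALSE)
  }
  rows <- lapply(sort(candidate_days), function(wd) {
    series <- window_networks(scans, wd, wd, span = span)
    dens <- vapply(series$snapshot, edge_density, 1)
    noise <- mean(vapply(seq_len(nrow(series)), function(i) {
      sc <- scans[scans$date >= series$window_start[i] &
                    scans$date <= series$window_end[i], ]
      if (nrow(sc) < 2) return(NA_real_)
      v <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(sc), nrow(sc), replace = TRUE)
        edge_density(network_snapshot(sc[idx, ], attr(series, "units")))
      }, 1)
      stats::var(v)
    }, 1), na.rm = TRUE)
    tibble::tibble(
      window_days = wd, n_windows = nrow(series),
      signal = stats::var(dens), noise = noise,
      ratio = if (noise > 0) stats::var(dens) / noise else NA_real_
    )
  })
  diagnostics <- dplyr::bind_rows(rows)
  score <- if (criterion == "signal_noise") diagnostics$ratio else diagnostics$signal
  score[is.na(score)] <- -Inf
  list(window_days = diagnostics$window_days[which.max(score)],
       diagnostics = diagnostics)
}

#' Export a network series
#'
#' `write_edge_lists()` writes all windows' edges
#' (`window_start,unit_a,unit_b,ai`); `write_metric_series()` writes a long
#' metric table (`window_start,metric,value`).
#'
#' @param series a `network_series`.
#' @param path output CSV path.
#' @export
write_edge_lists <- function(series, path) {
  rows <- lapply(seq_len(nrow(series)), function(i) {
    e <- series$snapshot[[i]]$edges
    if (!nrow(e)) return(NULL)
    cbind(window_start = format(series$window_start[i]), as.data.frame(e))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_lists
#' @export
write_metric_series <- function(series, path) {
  m <- network_metrics(series)
  long <- tidyr::pivot_longer(m, -"window_start", names_to = "metric",
                              values_to = "value")
  utils::write.csv(as.data.frame(long), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot per-window network metrics
#'
#' @param object a `network_series`.
#' @param metrics which metric columns of [network_metrics()] to show.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot network_series
#' @export
autoplot.network_series <- function(object, metrics = c("density", "clustering"),
                                    ...) {
  m <- network_metrics(object)
  long <- tidyr::pivot_longer(m[, c("window_start", metrics)], -"window_start",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window_start, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "window start", y = NULL) +
    ggplot2::theme_minimal()
}
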