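# Sliding windows, metrics vs enumeration oracles, cosine similarity,
# bootstrap intervals, window-size selection.

test_that("window arithmetic matches the study span", {
  # inclusive span 2017-08-28 .. 2019-05-13, 31-day window and shift
  span <- as.Date(c("2017-08-28", "2019-05-13"))
  scans <- make_scans(c("A", "B"), dates = span[1])
  series <- window_networks(scans, 31, 31, span = span, units = c("A", "B"))
  expect_equal(nrow(series), 20)
  expect_equal(series$window_start[1], span[1])
  expect_true(max(series$window_end) <= span[2])

  one <- window_networks(scans, 31, 31, span = c(span[1], span[1] + 30),
                         units = c("A", "B"))
  expect_equal(nrow(one), 1)

  # overlapping windows: floor((span - window)/shift) + 1
  span2 <- c(span[1], span[1] + 99)   # 100 days
  s2 <- window_networks(scans, 31, 15, span = span2, units = c("A", "B"))
  expect_equal(nrow(s2), (100 - 31) %/% 15 + 1)
  expect_error(window_networks(scans, 31, 31, span = c(span[1], span[1] + 10)),
               "shorter than one window")
})

test_that("windows partition scans when shift equals window", {
  set.seed(3)
  scans <- random_scans(60, 4, days = as.Date("2018-01-01") + 0:59)
  series <- window_networks(scans, 10, 10)
  expect_equal(sum(series$n_scans), nrow(scans))
  # chronological and non-overlapping
  expect_true(all(diff(series$window_start) == 10))
})

test_that("node and network metrics match forced examples", {
  units <- c("C0", "L1", "L2", "L3")
  w <- matrix(0, 4, 4, dimnames = list(units, units))
  w["C0", c("L1", "L2", "L3")] <- 0.5
  w <- pmax(w, t(w))
  star <- snapshot_from_matrix(w)
  expect_equal(node_degree(star, "C0"), 3)
  expect_equal(node_strength(star, "C0"), 1.5)
  expect_equal(node_degree(star, "L1"), 1)
  expect_equal(edge_density(star), 3 / 6)
  expect_equal(clustering_coefficient(star), 0)
  expect_error(node_degree(star, "nope"), "unknown unit")

  tri <- snapshot_from_matrix(matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
                                     dimnames = list(LETTERS[1:3], LETTERS[1:3])))
  expect_equal(clustering_coefficient(tri), 1)
  expect_equal(edge_density(tri), 1)

  iso <- snapshot_from_matrix(matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(node_degree(iso, "A"), 0)
  expect_equal(node_strength(iso, "A"), 0)
  expect_equal(edge_density(iso), 0)
})

test_that("density and transitivity equal enumeration on random graphs", {
  set.seed(37)
  for (rep in 1:60) {
    n <- sample(3:6, 1)
    adj <- matrix(stats::rbinom(n * n, 1, 0.5), n, n)
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    diag(adj) <- 0
    dimnames(adj) <- list(paste0("U", 1:n), paste0("U", 1:n))
    snap <- snapshot_from_matrix(adj * 0.7)
    expect_equal(edge_density(snap), brute_density(adj))
    cc <- clustering_coefficient(snap)
    bt <- brute_transitivity(adj)
    if (is.na(bt)) expect_true(is.na(cc)) else expect_equal(cc, bt)
    for (u in rownames(adj)) {
      expect_equal(node_degree(snap, u), sum(adj[u, ] > 0))
      expect_equal(node_strength(snap, u), sum(adj[u, ] * 0.7))
    }
  }
})

test_that("cosine similarity anchors and hand-computed case", {
  units <- c("A", "B", "C", "D")
  w1 <- matrix(0, 4, 4, dimnames = list(units, units))
  w1["A", "B"] <- w1["B", "A"] <- 1
  w2 <- w1
  w2["C", "D"] <- w2["D", "C"] <- 1
  n1 <- snapshot_from_matrix(w1)
  n2 <- snapshot_from_matrix(w2)
  expect_equal(cosine_similarity(n1, n1), 1)
  expect_equal(cosine_similarity(n1, n2), 1 / sqrt(2))

  w3 <- matrix(0, 4, 4, dimnames = list(units, units))
  w3["C", "D"] <- w3["D", "C"] <- 0.4
  expect_equal(cosine_similarity(n1, snapshot_from_matrix(w3)), 0)

  empty <- snapshot_from_matrix(matrix(0, 4, 4, dimnames = list(units, units)))
  expect_equal(cosine_similarity(n1, empty), 0)
})

test_that("cosine similarity is symmetric, scale-blind, padding-invariant", {
  set.seed(41)
  units <- LETTERS[1:5]
  mk <- function(n_units) {
    w <- matrix(stats::runif(n_units^2) * (stats::runif(n_units^2) < 0.5),
                n_units, n_units,
                dimnames = list(LETTERS[1:n_units], LETTERS[1:n_units]))
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    diag(w) <- 0
    w
  }
  for (rep in 1:10) {
    w1 <- mk(5); w2 <- mk(5)
    a <- snapshot_from_matrix(w1); b <- snapshot_from_matrix(w2)
    expect_equal(cosine_similarity(a, b), cosine_similarity(b, a))
    expect_equal(cosine_similarity(a, snapshot_from_matrix(w1 * 3)), 1)
    # padding with an extra isolated unit changes nothing
    w1p <- rbind(cbind(w1, F1 = 0), F1 = 0)
    rownames(w1p) <- c(rownames(w1), "F1")
    expect_equal(cosine_similarity(snapshot_from_matrix(w1p), b),
                 cosine_similarity(a, b))
  }
})

test_that("stability series report lag-1 and to-first similarities", {
  set.seed(43)
  scans <- random_scans(60, 4, days = as.Date("2018-01-01") + 0:59)
  series <- window_networks(scans, 15, 15)
  lag1 <- stability_series(series, "lag1")
  tf <- stability_series(series, "to_first")
  expect_true(is.na(lag1$cosine[1]))
  expect_equal(tf$cosine[1], 1)
  expect_equal(lag1$cosine[2],
               cosine_similarity(series$snapshot[[1]], series$snapshot[[2]]))
  # identical snapshots throughout -> all 1
  const <- make_scans(replicate(12, c("A", "B"), simplify = FALSE),
                      dates = as.Date("2018-01-01") + rep(0:5, each = 2))
  cs <- window_networks(const, 2, 2)
  expect_equal(stability_series(cs, "to_first")$cosine, rep(1, 3))
  expect_equal(stability_series(cs, "lag1")$cosine[-1], rep(1, 2))
})

test_that("bootstrap interval is a reproducible highest-density interval", {
  const <- make_scans(replicate(10, c("A", "B", "C"), simplify = FALSE))
  ci <- bootstrap_ci(const, edge_density, n_boot = 50, seed = 1)
  expect_equal(ci$lower, ci$upper)  # constant statistic
  expect_equal(ci$lower, 1)

  set.seed(47)
  scans <- random_scans(40, 4)
  a <- bootstrap_ci(scans, edge_density, n_boot = 60, seed = 9)
  b <- bootstrap_ci(scans, edge_density, n_boot = 60, seed = 9)
  expect_equal(a, b)
  point <- edge_density(network_snapshot(scans, sort(unique(c(scans$focal_unit,
                                                              unlist(scans$associates))))))
  expect_true(a$lower <= point && point <= a$upper)
})

test_that("the HDI is the shortest interval holding the requested mass", {
  set.seed(71)
  for (rep in 1:5) {
    x <- c(stats::rnorm(60, 0, 0.1), stats::runif(40, -2, 2))
    hdi <- clannet:::hdi_interval(x, 0.9)
    # brute force: narrowest window over any 90% of the sorted sample
    xs <- sort(x)
    k <- ceiling(0.9 * length(xs))
    widths <- xs[k:length(xs)] - xs[1:(length(xs) - k + 1)]
    expect_equal(hdi[2] - hdi[1], min(widths))
    expect_gte(mean(x >= hdi[1] & x <= hdi[2]), 0.9)
  }
})

test_that("window-size selection resolves a known density cycle", {
  # 60-day cycle: dense and sparse months alternate
  set.seed(53)
  days <- as.Date("2018-01-01") + 0:239
  phase <- as.integer(days - days[1]) %% 60 < 30
  sets <- lapply(seq_along(days), function(i) {
    units <- LETTERS[1:6]
    focal <- units[(i - 1) %% 6 + 1]
    p <- if (phase[i]) 0.65 else 0.05
    c(focal, setdiff(units, focal)[stats::runif(5) < p])
  })
  scans <- make_scans(sets, dates = days)
  sel <- select_window_size(scans, c(30, 60, 120), n_boot = 20, seed = 2)
  expect_lte(sel$window_days, 60)
  expect_equal(nrow(sel$diagnostics), 3)

  single <- select_window_size(scans, 30, n_boot = 10, seed = 2)
  expect_equal(single$window_days, 30)
  expect_error(select_window_size(scans, c(30, 1000), n_boot = 5),
               "longer than the study span")
})

test_that("metric and edge exports write tidy CSVs", {
  set.seed(59)
  scans <- random_scans(40, 4, days = as.Date("2018-01-01") + 0:39)
  series <- window_networks(scans, 10, 10)
  dir <- withr::local_tempdir()
  write_edge_lists(series, file.path(dir, "edges.csv"))
  write_metric_series(series, file.path(dir, "metrics.csv"))
  edges <- utils::read.csv(file.path(dir, "edges.csv"))
  expect_true(all(c("window_start", "unit_a", "unit_b", "ai") %in% names(edges)))
  metrics <- utils::read.csv(file.path(dir, "metrics.csv"))
  expect_setequal(unique(metrics$metric),
                  c("density", "clustering", "mean_degree", "mean_strength"))
  m <- network_metrics(series)
  expect_equal(nrow(m), nrow(series))
  nm <- node_metrics(series)
  expect_equal(nrow(nm), nrow(series) * 4)
})
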