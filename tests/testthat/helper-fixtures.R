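# Shared test fixtures: compact scan construction and brute-force oracles.

# Build a scan tibble from presence sets given as character vectors whose
# first element is the focal unit; dates/times default to one scan per day.
make_scans <- function(..., dates = NULL, times = NULL) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is.character(sets[[1]])) {
    sets <- sets[[1]]
  }
  n <- length(sets)
  if (is.null(dates)) dates <- as.Date("2018-01-01") + seq_len(n) - 1
  if (is.null(times)) times <- rep("09:00", n)
  scan_table(
    date = dates, time = times,
    focal_unit = vapply(sets, function(s) s[[1]], ""),
    associates = lapply(sets, function(s) s[-1])
  )
}

# Random scan set over <= n_units units, one focal per scan.
random_scans <- function(n_scans, n_units, p = 0.4, days = NULL) {
  units <- LETTERS[seq_len(n_units)]
  sets <- lapply(seq_len(n_scans), function(i) {
    focal <- sample(units, 1)
    others <- setdiff(units, focal)
    c(focal, others[stats::runif(length(others)) < p])
  })
  if (is.null(days)) days <- as.Date("2018-01-01") + (seq_len(n_scans) - 1) %/% 5
  make_scans(sets, dates = days,
             times = sprintf("%02d:00", 7 + 2 * ((seq_len(n_scans) - 1) %% 5)))
}

# Brute-force AI for one dyad by looping over scans.
brute_ai <- function(scans, a, b) {
  joint <- 0; either <- 0
  for (i in seq_len(nrow(scans))) {
    pres <- unit_presence(scans[i, ])
    ina <- a %in% pres; inb <- b %in% pres
    if (ina || inb) either <- either + 1
    if (ina && inb) joint <- joint + 1
  }
  if (either == 0) NA_real_ else joint / either
}

# Brute-force density and global transitivity from a 0/1 adjacency matrix.
brute_density <- function(adj) {
  n <- nrow(adj)
  sum(adj[upper.tri(adj)] > 0) / choose(n, 2)
}

brute_transitivity <- function(adj) {
  n <- nrow(adj)
  adj <- (adj > 0) + 0
  triangles <- 0; triples <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && j < k) {
      e <- adj[i, j] + adj[j, k] + adj[i, k]
      if (e == 3) triangles <- triangles + 1
    }
  }
  for (centre in seq_len(n)) {
    nb <- sum(adj[centre, ]) - adj[centre, centre]
    triples <- triples + choose(nb, 2)
  }
  if (triples == 0) return(NA_real_)
  3 * triangles / triples
}

# Independent cophenetic similarity via explicit lowest-common-merge search
# on the hclust merge table.
brute_cophenetic <- function(tree) {
  hc <- tree$hclust
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  out <- matrix(NA_real_, n, n, dimnames = list(hc$labels, hc$labels))
  for (m in seq_len(nrow(hc$merge))) {
    side <- function(v) if (v < 0) -v else members[[v]]
    l <- side(hc$merge[m, 1]); r <- side(hc$merge[m, 2])
    members[[m]] <- c(l, r)
    for (i in l) for (j in r) {
      out[i, j] <- out[j, i] <- tree$height_ai[m]
    }
  }
  out
}

# Snapshot wrapper around a weighted adjacency matrix (units from dimnames).
snapshot_from_matrix <- function(w) {
  units <- rownames(w)
  scansets <- list()
  am <- structure(
    list(units = units, ai = w + diag(NA_real_, nrow(w)),
         defined = matrix(TRUE, nrow(w), ncol(w), dimnames = dimnames(w)) &
           !diag(TRUE, nrow(w)),
         joint = w, n_union = (w > -1) + 0,
         sightings = stats::setNames(rep(1, nrow(w)), units),
         n_scans = 1L, period = NULL, denominator = "union"),
    class = "assoc_matrix"
  )
  d <- tidy(am)
  structure(
    list(window = NULL, units = units, matrix = am,
         edges = d[!is.na(d$ai) & d$ai > 0, c("unit_a", "unit_b", "ai")],
         n_scans = 1L),
    class = "network_snapshot"
  )
}

# Exact Wilcoxon one-sided p by direct enumeration of sign vectors,
# recomputing the statistic from the raw differences each time.
brute_wilcoxon <- function(baseline, dyad) {
  d <- dyad - baseline
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  total <- 0; hits <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(mask))[seq_len(n)]
    w <- sum(r[signs == 1])
    total <- total + 1
    if (w >= w_obs - 1e-12) hits <- hits + 1
  }
  hits / total
}

# Exhaustive Spearman permutation p for small n (two-sided on |rho|).
brute_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- combinat_permutations(length(y))
  vals <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
  mean(abs(vals) >= abs(rho_obs) - 1e-12)
}

combinat_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_permutations(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}
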