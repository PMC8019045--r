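# Dispersal month assignment, transfer counts, Monte-Carlo Spearman,
# exact Wilcoxon, and post-dispersal comparisons.

test_that("dispersal month is the month holding most of the date range", {
  expect_equal(assign_dispersal_month("2018-01-25", "2018-02-10"), "2018-02")
  expect_equal(assign_dispersal_month("2018-03-05", "2018-03-20"), "2018-03")
  # 15 days in April (16th-30th) vs 15 in May (1st-15th): tie -> earlier
  expect_equal(assign_dispersal_month("2018-04-16", "2018-05-15"), "2018-04")
  expect_error(assign_dispersal_month("2018-05-10", "2018-05-01"), "inversion")
})

test_that("month assignment is invariant to shrinking within the winner", {
  set.seed(7)
  for (rep in 1:15) {
    start <- as.Date("2018-01-01") + sample(0:330, 1)
    end <- start + sample(0:20, 1)
    m <- assign_dispersal_month(start, end)
    # shrink the range to its intersection with the winning month
    days <- seq(start, end, by = "day")
    inside <- days[date_month(days) == m]
    expect_equal(assign_dispersal_month(min(inside), max(inside)), m)
  }
})

test_that("monthly transfer counts zero-fill, exclude females, sum males", {
  span <- as.Date(c("2018-01-01", "2018-06-30"))
  five <- tibble::tibble(
    individual_id = paste0("M", 1:5), sex = "male",
    from_unit = "A", to_unit = "B",
    last_seen_origin = as.Date("2018-03-10"),
    first_seen_destination = as.Date("2018-03-12")
  )
  counts <- monthly_transfer_counts(five, span)
  expect_equal(nrow(counts), 6)
  expect_equal(counts$male_transfers[counts$month == "2018-03"], 5)
  expect_equal(sum(counts$male_transfers), 5)

  none <- monthly_transfer_counts(five[0, ], span)
  expect_equal(none$male_transfers, rep(0L, 6))

  one_female <- five[1, ]
  one_female$sex <- "female"
  cf <- monthly_transfer_counts(one_female, span)
  expect_equal(sum(cf$male_transfers), 0)
})

test_that("Spearman rho anchors and Monte-Carlo p near the exact value", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_mc(x, x * 2 + 1, n_mc = 200, seed = 1)$rho, 1)
  expect_equal(spearman_mc(x, rev(x), n_mc = 200, seed = 1)$rho, -1)
  expect_error(spearman_mc(x, rep(1, 6)), "zero variance")
  expect_error(spearman_mc(1:4, 1:4), "at least 5")

  # tied series: MC p within 2 SE of the exhaustive permutation p (6! = 720)
  y <- c(0, 0, 1, 0, 2, 1)
  exact <- brute_spearman_p(x, y)
  mc <- spearman_mc(x, y, n_mc = 4000, seed = 3)
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(mc$p_value - exact), 2 * se + 1 / 4000)
})

test_that("Bonferroni correction matches the conventional display", {
  expect_equal(bonferroni(0.05, 3)$display, 0.017)
  expect_equal(bonferroni(0.05, 3)$alpha, 0.05 / 3)
  expect_equal(bonferroni(0.05, 1)$alpha, 0.05)
  expect_equal(bonferroni(0.05, 5)$alpha, 0.01)
})

test_that("exact Wilcoxon p matches enumeration for all n <= 10", {
  expect_equal(wilcoxon_one_sample(c(0.1, 0.2, 0.3), 0.5), 1 / 8)
  expect_equal(wilcoxon_one_sample(c(0.1, 0.15, 0.2, 0.25, 0.3), 0.5), 1 / 32)
  set.seed(11)
  for (n in 3:10) {
    for (rep in 1:4) {
      base <- round(stats::runif(n, 0, 0.5), 2)  # rounding induces ties
      dyad <- round(stats::runif(1, 0, 0.6), 2)
      if (all(dyad == base)) next
      expect_equal(wilcoxon_one_sample(base, dyad), brute_wilcoxon(base, dyad),
                   info = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("exact Wilcoxon agrees with stats::wilcox.test on tie-free data", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    base <- stats::runif(n)
    dyad <- stats::runif(1, 0.3, 1.4)
    ref <- stats::wilcox.test(dyad - base, alternative = "greater",
                              exact = TRUE)$p.value
    expect_equal(wilcoxon_one_sample(base, dyad), ref, tolerance = 1e-12)
  }
})

test_that("large-sample Wilcoxon approximation is close to the exact tail", {
  set.seed(17)
  base <- stats::runif(15, 0, 1)
  dyad <- 0.8
  exact <- wilcoxon_one_sample(base, dyad)           # n = 15: enumeration
  approx_p <- clannet:::wilcoxon_one_sample(c(base, base[1] + 1e-9), dyad)
  expect_lt(abs(exact - approx_p), 0.05)
  expect_true(wilcoxon_one_sample(stats::runif(20), 2) < 0.001)
  expect_error(wilcoxon_one_sample(c(0.2, 0.2), 0.2), "non-zero differences")
})

test_that("post-dispersal dyad AI is the month-restricted simple AI", {
  ev <- tibble::tibble(individual_id = "M1", sex = "male", from_unit = "A",
                       to_unit = "B", last_seen_origin = as.Date("2018-01-10"),
                       first_seen_destination = as.Date("2018-01-12"))
  feb <- make_scans(
    c("A", "B"), c("A", "B"), c("A"), c("B"), c("A", "B"), c("C"),
    dates = as.Date("2018-02-01") + 0:5
  )
  expect_equal(post_dispersal_dyad_ai(ev, feb, 1), 3 / 5)
  expect_true(is.na(post_dispersal_dyad_ai(ev, feb, 2)))  # no March scans
  always <- make_scans(c("A", "B"), dates = as.Date("2018-02-10"))
  expect_equal(post_dispersal_dyad_ai(ev, always, 1), 1)
})

test_that("baseline set is the transfer-month associates of both units", {
  ev <- tibble::tibble(individual_id = "M1", sex = "male", from_unit = "A",
                       to_unit = "B", last_seen_origin = as.Date("2018-01-10"),
                       first_seen_destination = as.Date("2018-01-12"))
  jan <- make_scans(
    c("A", "C"), c("A", "D"), c("A", "E"), c("B", "C"), c("B", "F"),
    dates = as.Date("2018-01-05") + 0:4
  )
  # evaluation in the transfer month itself: A assoc with C,D,E; B with C,F
  base0 <- baseline_ais(ev, jan, month_offset = 0)
  expect_length(base0, 5)
  # only the focal dyad associates -> empty control set
  lonely <- make_scans(c("A", "B"), c("A", "B"), dates = as.Date("2018-01-05") + 0:1)
  expect_length(baseline_ais(ev, lonely, 0), 0)
})

test_that("post-dispersal analysis flags boundaries and groups parallel males", {
  ev <- tibble::tibble(
    individual_id = c("M1", "M2"), sex = "male", from_unit = "A", to_unit = "B",
    last_seen_origin = as.Date("2018-01-10"),
    first_seen_destination = as.Date("2018-01-12")
  )
  set.seed(19)
  scans <- random_scans(120, 6, p = 0.3,
                        days = as.Date("2018-01-01") + (0:119) %/% 2)
  out <- post_dispersal_analysis(ev, scans)
  expect_equal(nrow(out), 3)           # one event despite two males
  expect_equal(out$offset, 1:3)
  # event in the final study month: offsets beyond the data flagged missing
  late <- ev[1, ]
  late$last_seen_origin <- as.Date("2018-02-20")
  late$first_seen_destination <- as.Date("2018-02-22")
  out2 <- post_dispersal_analysis(late, scans)
  expect_true(all(is.na(out2$dyad_ai[out2$offset >= 2])))
  expect_false(any(out2$significant[out2$offset >= 2]))
  expect_equal(nrow(post_dispersal_analysis(ev[0, ], scans)), 0)
})

test_that("bond preset elevates the dyad over baseline in early offsets", {
  ev <- tibble::tibble(individual_id = "M001", sex = "male",
                       from_unit = "U01", to_unit = "U02",
                       last_seen_origin = as.Date("2017-09-14"),
                       first_seen_destination = as.Date("2017-09-15"))
  gap <- vapply(1:8, function(s) {
    set.seed(s)
    sc <- simulate_scans(society_preset("bond"), dispersals = ev)
    out <- post_dispersal_analysis(ev, sc)
    out$dyad_ai[1] - out$baseline_mean[1]
  }, 1)
  expect_true(all(gap > 0))
})
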