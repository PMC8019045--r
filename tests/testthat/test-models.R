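# AR1 regressions: exact fits, OLS/GLS oracles, nlme cross-checks, R squared.

sim_ar1 <- function(n, beta, phi, sigma = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n)
  e <- if (phi == 0) stats::rnorm(n, 0, sigma) else {
    as.numeric(stats::arima.sim(list(ar = phi), n, sd = sigma))
  }
  tibble::tibble(x = x, y = beta[1] + beta[2] * x + e)
}

test_that("noiseless linear data are fit exactly with vanishing CI width", {
  z <- stats::rnorm(30)
  d <- tibble::tibble(z_fruit = z, y = 0.5 + 0.08 * z)
  fit <- fit_network_level(d, "y", "z_fruit")
  co <- tidy(fit)
  expect_equal(co$estimate[co$term == "z_fruit"], 0.08, tolerance = 1e-7)
  expect_equal(co$estimate[co$term == "(Intercept)"], 0.5, tolerance = 1e-7)
  expect_lt(co$conf.high[2] - co$conf.low[2], 1e-5)
  r2 <- r_squared(fit, n_boot = 20, seed = 1)
  expect_equal(r2$estimate, 1, tolerance = 1e-6)
})

test_that("with phi = 0 the ML fit reduces to ordinary least squares", {
  set.seed(71)
  d <- sim_ar1(60, c(1, 0.5), phi = 0)
  ols <- stats::lm(y ~ x, data = d)
  pr <- clannet:::ar1_profile(d$y, cbind(1, x = d$x), phi = 0)
  expect_equal(unname(pr$beta), unname(stats::coef(ols)), tolerance = 1e-8)
})

test_that("with phi fixed at truth the fit equals quasi-differenced OLS", {
  set.seed(73)
  phi <- 0.6
  d <- sim_ar1(80, c(0.3, 0.7), phi = phi)
  X <- cbind(`(Intercept)` = 1, x = d$x)
  pr <- clannet:::ar1_profile(d$y, X, phi = phi)
  # independent oracle: plain lm on the quasi-differenced data
  n <- nrow(d)
  s1 <- sqrt(1 - phi^2)
  ty <- c(s1 * d$y[1], d$y[-1] - phi * d$y[-n])
  tX <- rbind(s1 * X[1, ], X[-1, ] - phi * X[-n, ])
  oracle <- stats::lm.fit(tX, ty)
  expect_equal(unname(pr$beta), unname(oracle$coefficients), tolerance = 1e-10)
})

test_that("network-level estimates agree with nlme::gls", {
  skip_if_not_installed("nlme")
  set.seed(79)
  d <- sim_ar1(80, c(0.2, 0.5), phi = 0.5)
  fit <- fit_network_level(d, "y", "x")
  g <- nlme::gls(y ~ x, data = d, correlation = nlme::corAR1(), method = "ML")
  expect_equal(unname(tidy(fit)$estimate), unname(stats::coef(g)),
               tolerance = 1e-3)
  expect_equal(fit$phi, stats::coef(g$modelStruct$corStruct, unconstrained = FALSE),
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("ridge penalty shrinks slopes toward zero like a normal(0,1) prior", {
  set.seed(83)
  d <- sim_ar1(15, c(0, 2), phi = 0)
  plain <- fit_network_level(d, "y", "x")
  ridge <- fit_network_level(d, "y", "x", ridge = TRUE)
  b_plain <- tidy(plain)$estimate[2]
  b_ridge <- tidy(ridge)$estimate[2]
  expect_lt(abs(b_ridge), abs(b_plain))
  expect_gt(abs(b_ridge), 0)
})

test_that("node-level fit recovers parameters and matches nlme::lme", {
  skip_if_not_installed("nlme")
  set.seed(89)
  n_units <- 8; n_win <- 20
  tau <- 1; phi <- 0.4; beta <- c(2, 1.5)
  d <- dplyr::bind_rows(lapply(seq_len(n_units), function(i) {
    x <- stats::rnorm(n_win)
    e <- as.numeric(stats::arima.sim(list(ar = phi), n_win, sd = 0.8))
    tibble::tibble(unit = paste0("U", i), t = seq_len(n_win), x = x,
                   y = beta[1] + stats::rnorm(1, 0, tau) + beta[2] * x + e)
  }))
  fit <- fit_node_level(d, "y", "x", unit = "unit", time = "t")
  co <- tidy(fit)
  expect_equal(co$estimate[co$term == "x"], beta[2], tolerance = 0.1)
  expect_gt(fit$tau, 0.3)
  expect_gt(fit$phi, 0.1)

  lme_fit <- nlme::lme(y ~ x, random = ~ 1 | unit, data = d,
                       correlation = nlme::corAR1(form = ~ t | unit),
                       method = "ML")
  expect_equal(co$estimate[co$term == "x"],
               unname(nlme::fixef(lme_fit)["x"]), tolerance = 1e-2)
  expect_equal(fit$phi,
               stats::coef(lme_fit$modelStruct$corStruct, unconstrained = FALSE),
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("permuting unit labels leaves node-level fixed effects unchanged", {
  set.seed(97)
  d <- dplyr::bind_rows(lapply(1:5, function(i) {
    tibble::tibble(unit = paste0("U", i), t = 1:10, x = stats::rnorm(10),
                   y = stats::rnorm(10) + i / 2)
  }))
  f1 <- fit_node_level(d, "y", "x", unit = "unit", time = "t")
  relabel <- stats::setNames(paste0("Z", 5:1), paste0("U", 1:5))
  d2 <- d; d2$unit <- unname(relabel[d$unit])
  f2 <- fit_node_level(d2, "y", "x", unit = "unit", time = "t")
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-6)
})

test_that("with tau = 0 and phi = 0 node and network fits agree on pooled data", {
  set.seed(101)
  d <- dplyr::bind_rows(lapply(1:6, function(i) {
    tibble::tibble(unit = paste0("U", i), t = 1:12, x = stats::rnorm(12))
  }))
  d$y <- 0.4 + 0.9 * d$x + stats::rnorm(nrow(d), 0, 0.5)
  fn <- fit_node_level(d, "y", "x", unit = "unit", time = "t")
  fp <- fit_network_level(d, "y", "x")
  expect_equal(tidy(fn)$estimate, tidy(fp)$estimate, tolerance = 0.02)
})

test_that("likelihood at the ML estimate is at least that at the truth", {
  for (s in 1:5) {
    set.seed(s)
    d <- sim_ar1(50, c(0.2, 0.5), phi = 0.6)
    X <- cbind(1, x = d$x)
    fit <- fit_network_level(d, "y", "x")
    ll_hat <- clannet:::ar1_concentrated_loglik(d$y, X, fit$phi)
    ll_true <- clannet:::ar1_concentrated_loglik(d$y, X, 0.6)
    expect_gte(ll_hat, ll_true - 1e-9)
  }
})

test_that("units with too few observations are dropped with a warning", {
  d <- dplyr::bind_rows(
    tibble::tibble(unit = "A", t = 1:8, x = stats::rnorm(8), y = stats::rnorm(8)),
    tibble::tibble(unit = "B", t = 1:8, x = stats::rnorm(8), y = stats::rnorm(8)),
    tibble::tibble(unit = "C", t = 1:2, x = stats::rnorm(2), y = stats::rnorm(2))
  )
  expect_warning(fit <- fit_node_level(d, "y", "x", unit = "unit", time = "t"),
                 "dropped: C")
  expect_equal(fit$n_obs, 16)
})

test_that("R squared recovers a known variance decomposition", {
  # var(fitted) ~ beta^2 = 0.36, residual 1 -> R2 ~ 0.265; average over seeds
  r2s <- vapply(1:10, function(s) {
    d <- sim_ar1(400, c(0, 0.6), phi = 0, sigma = 1, seed = s)
    fit <- fit_network_level(d, "y", "x")
    r_squared(fit, n_boot = 2, seed = s)$estimate
  }, 1)
  expect_lt(abs(mean(r2s) - 0.36 / 1.36), 0.04)
  d <- sim_ar1(400, c(0, 0.6), phi = 0, sigma = 1, seed = 1)
  r2 <- r_squared(fit_network_level(d, "y", "x"), n_boot = 100, seed = 5)
  expect_true(r2$lower <= r2$estimate && r2$estimate <= r2$upper)
})

test_that("fit export mirrors the coefficient-table layout", {
  set.seed(107)
  d <- sim_ar1(40, c(0.1, 0.4), phi = 0.3)
  fit <- fit_network_level(d, "y", "x")
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, path, r2 = r_squared(fit, n_boot = 20, seed = 1))
  back <- jsonlite::read_json(path)
  expect_equal(length(back$coefficients), 2)
  expect_setequal(names(back$coefficients[[1]]),
                  c("term", "estimate", "error", "lower", "upper"))
  expect_true(back$phi > -1 && back$phi < 1)
  g <- glance(fit)
  expect_equal(g$n_obs, 40)
})
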