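# Regression of network metrics on standardized ecological covariates with
# AR1-autocorrelated errors.
#
# Network level: y_t = X_t b + e_t, e_t = phi * e_{t-1} + n_t, n ~ N(0, s^2),
# fit by exact maximum likelihood: quasi-differencing makes the innovations
# iid given phi, so beta and sigma have closed forms and the likelihood is
# concentrated into a 1-D search over phi.
#
# Node level adds a unit random intercept, b_i ~ N(0, tau^2), with the AR1
# applying within each unit's residual series independently. The marginal
# covariance per unit is s^2 (R(phi) + gamma * J), gamma = tau^2 / s^2, and
# the likelihood is concentrated into a 2-D search over (phi, gamma).
#
# An optional ridge penalty on the slopes, equivalent to independent
# normal(0, 1) priors, is available for standardized predictors.

ar1_transform <- function(y, X, phi) {
  n <- length(y)
  s1 <- sqrt(1 - phi^2)
  ty <- c(s1 * y[1], y[-1] - phi * y[-n])
  tX <- rbind(s1 * X[1, , drop = FALSE], X[-1, , drop = FALSE] - phi * X[-n, , drop = FALSE])
  list(y = ty, X = tX)
}

# beta-hat and RSS given phi; ridge adds lambda on slope columns (not the
# intercept), lambda in innovation-variance units
ar1_profile <- function(y, X, phi, ridge_lambda = 0) {
  tr <- ar1_transform(y, X, phi)
  D <- diag(c(0, rep(ridge_lambda, ncol(X) - 1)), ncol(X))
  XtX <- crossprod(tr$X) + D
  beta <- solve(XtX, crossprod(tr$X, tr$y))
  resid <- tr$y - tr$X %*% beta
  list(beta = drop(beta), rss = sum(resid^2), XtX = XtX, n = length(y))
}

ar1_concentrated_loglik <- function(y, X, phi, ridge_lambda = 0) {
  pr <- ar1_profile(y, X, phi, ridge_lambda)
  n <- pr$n
  sigma2 <- pr$rss / n
  -n / 2 * (log(2 * pi * sigma2) + 1) + 0.5 * log(1 - phi^2)
}

#' Fit a network-level AR1 regression
#'
#' Linear regression of a per-window network metric on standardized
#' ecological covariates with AR1-autocorrelated errors, fit by maximum
#' likelihood. 95% CIs use the t distribution on the residual degrees of
#' freedom with the GLS covariance at the estimated AR1 coefficient.
#' Windows with a missing response (for example, undefined clustering
#' coefficient) are dropped listwise with a message.
#'
#' @param data tibble with one row per window.
#' @param response name of the metric column.
#' @param predictors names of the (standardized) covariate columns.
#' @param ridge if `TRUE`, penalize the slopes like independent normal(0, 1)
#'   priors (appropriate only for standardized predictors).
#' @param level CI level.
#' @return an `ar1_fit` with `coefficients` tibble (`term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`), `phi`, `sigma` (innovation SD),
#'   `logLik`, `n_obs`, `fitted`, `residuals`, and `method = "ml"`.
#' @export
fit_network_level <- function(data, response,
                              predictors = c("z_fruit", "z_leaf", "z_rain"),
                              ridge = FALSE, level = 0.95) {
  y <- data[[response]]
  keep <- stats::complete.cases(data[, c(response, predictors)])
  if (sum(!keep)) message(sum(!keep), " window(s) with missing values dropped")
  y <- y[keep]
  X <- cbind(`(Intercept)` = 1, as.matrix(data[keep, predictors]))
  if (!all(is.finite(y))) stop("non-finite response values", call. = FALSE)
  if (length(y) < ncol(X) + 2) stop("fewer observations than parameters", call. = FALSE)
  lambda <- if (ridge) 1 else 0   # sigma^2 / prior variance, in RSS units: see below
  # with normal(0,1) priors the penalty is sigma^2 * sum(beta^2); iterate the
  # sigma^2 plug-in since the concentrated form depends on it
  ridge_lambda <- 0
  for (it in seq_len(if (ridge) 5 else 1)) {
    opt <- stats::optimize(function(phi) {
      -ar1_concentrated_loglik(y, X, phi, ridge_lambda)
    }, interval = c(-0.98, 0.98))
    phi <- opt$minimum
    pr <- ar1_profile(y, X, phi, ridge_lambda)
    sigma2 <- pr$rss / pr$n
    if (!ridge) break
    ridge_lambda <- sigma2 * lambda
  }
  df <- pr$n - ncol(X)
  sigma2_df <- pr$rss / df
  vc <- sigma2_df * solve(pr$XtX)
  se <- sqrt(diag(vc))
  tq <- stats::qt(1 - (1 - level) / 2, df)
  fitted_fixed <- drop(X %*% pr$beta)
  out <- structure(
    list(
      coefficients = tibble::tibble(
        term = colnames(X), estimate = unname(pr$beta), std.error = unname(se),
        conf.low = unname(pr$beta - tq * se),
        conf.high = unname(pr$beta + tq * se)
      ),
      phi = phi, sigma = sqrt(sigma2), tau = 0,
      logLik = ar1_concentrated_loglik(y, X, phi, ridge_lambda),
      n_obs = pr$n, method = "ml", level = level, ridge = ridge,
      fitted = fitted_fixed, residuals = y - fitted_fixed,
      y = y, X = X, unit = NULL, kind = "network"
    ),
    class = "ar1_fit"
  )
  out
}

# negative concentrated loglik for the node-level model at
# theta = (atanh(phi), log gamma); returns environment with components when
# `detail` is TRUE
node_loglik <- function(theta, y_list, X_list, detail = FALSE) {
  phi <- tanh(theta[1])
  gamma <- exp(theta[2])
  p <- ncol(X_list[[1]])
  XtWX <- matrix(0, p, p)
  XtWy <- numeric(p)
  Ws <- list()
  logdet <- 0
  for (i in seq_along(y_list)) {
    n_i <- length(y_list[[i]])
    R <- phi^abs(outer(seq_len(n_i), seq_len(n_i), "-"))  # AR1 correlation
    V <- R + gamma
    ch <- chol(V)
    logdet <- logdet + 2 * sum(log(diag(ch)))
    W <- chol2inv(ch)
    Ws[[i]] <- W
    XtWX <- XtWX + t(X_list[[i]]) %*% W %*% X_list[[i]]
    XtWy <- XtWy + t(X_list[[i]]) %*% W %*% y_list[[i]]
  }
  beta <- solve(XtWX, XtWy)
  q <- 0
  for (i in seq_along(y_list)) {
    r <- y_list[[i]] - X_list[[i]] %*% beta
    q <- q + drop(t(r) %*% Ws[[i]] %*% r)
  }
  N <- sum(lengths(y_list))
  sigma2 <- q / N
  ll <- -N / 2 * (log(2 * pi * sigma2) + 1) - logdet / 2
  if (!detail) return(-ll)
  list(loglik = ll, beta = drop(beta), sigma2 = sigma2, phi = phi,
       gamma = gamma, XtWX = XtWX, N = N)
}

#' Fit a node-level AR1 mixed model
#'
#' Multi-level regression of a per-window per-unit metric on standardized
#' covariates with a unit random intercept and AR1 errors within each unit's
#' series, fit by maximum likelihood.
#'
#' @param data tibble with one row per unit x window.
#' @param response metric column name.
#' @param predictors covariate column names.
#' @param unit unit-identifier column name.
#' @param time ordering column name (window start).
#' @param level CI level.
#' @return an `ar1_fit` with `tau` (random-intercept SD) alongside the
#'   network-level fields.
#' @export
fit_node_level <- function(data, response,
                           predictors = c("z_fruit", "z_leaf", "z_rain"),
                           unit = "unit", time = "window_start", level = 0.95) {
  keep <- stats::complete.cases(data[, c(response, predictors)])
  if (sum(!keep)) message(sum(!keep), " row(s) with missing values dropped")
  data <- data[keep, ]
  data <- data[order(data[[unit]], data[[time]]), ]
  counts <- table(data[[unit]])
  small <- names(counts)[counts < 3]
  if (length(small)) {
    warning("unit(s) with < 3 observations dropped: ",
            paste(small, collapse = ", "), call. = FALSE)
    data <- data[!data[[unit]] %in% small, ]
  }
  ids <- unique(data[[unit]])
  if (length(ids) < 2) stop("need at least 2 units", call. = FALSE)
  if (length(unique(data[[time]])) < 2) stop("need more than one window", call. = FALSE)
  y_list <- split(data[[response]], factor(data[[unit]], levels = ids))
  Xmat <- cbind(`(Intercept)` = 1, as.matrix(data[, predictors]))
  X_list <- lapply(split(seq_len(nrow(data)), factor(data[[unit]], levels = ids)),
                   function(ix) Xmat[ix, , drop = FALSE])
  opt <- stats::optim(c(0, 0), node_loglik, y_list = y_list, X_list = X_list,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  fit <- node_loglik(opt$par, y_list, X_list, detail = TRUE)
  p <- ncol(Xmat)
  df <- fit$N - p - length(ids)   # conservative: fixed effects + intercepts
  vc <- fit$sigma2 * fit$N / max(df, 1) * solve(fit$XtWX)
  se <- sqrt(diag(vc))
  tq <- stats::qt(1 - (1 - level) / 2, max(df, 1))
  beta <- fit$beta
  # BLUP random intercepts for fitted values
  blup <- vapply(seq_along(ids), function(i) {
    r <- y_list[[i]] - X_list[[i]] %*% beta
    n_i <- length(r)
    # E[b_i | y] under V = sigma2 (R + gamma J): gamma 1' W r * sigma2 ratio
    R <- fit$phi^abs(outer(seq_len(n_i), seq_len(n_i), "-"))
    W <- solve(R + fit$gamma)
    fit$gamma * sum(W %*% r)
  }, 1)
  fitted_fixed <- drop(Xmat %*% beta) + blup[match(data[[unit]], ids)]
  structure(
    list(
      coefficients = tibble::tibble(
        term = colnames(Xmat), estimate = unname(beta), std.error = unname(se),
        conf.low = unname(beta - tq * se), conf.high = unname(beta + tq * se)
      ),
      phi = fit$phi, sigma = sqrt(fit$sigma2),
      tau = sqrt(fit$gamma * fit$sigma2),
      logLik = fit$loglik, n_obs = fit$N, method = "ml", level = level,
      ridge = FALSE, fitted = fitted_fixed,
      residuals = data[[response]] - fitted_fixed,
      y = data[[response]], X = Xmat, unit = data[[unit]], kind = "node"
    ),
    class = "ar1_fit"
  )
}

#' @export
print.ar1_fit <- function(x, ...) {
  cat(sprintf("AR1 %s-level fit (ML): n = %d, phi = %.3f, sigma = %.3f",
              x$kind, x$n_obs, x$phi, x$sigma))
  if (x$kind == "node") cat(sprintf(", tau = %.3f", x$tau))
  cat("\n")
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Tidy and summarize AR1 fits
#'
#' `tidy()` returns the coefficient table (`term`, `estimate`, `std.error`,
#' `conf.low`, `conf.high`); `glance()` returns one row of model-level
#' summaries.
#'
#' @param x an `ar1_fit`.
#' @param ... unused.
#' @method tidy ar1_fit
#' @export
tidy.ar1_fit <- function(x, ...) x$coefficients

#' @rdname tidy.ar1_fit
#' @method glance ar1_fit
#' @export
glance.ar1_fit <- function(x, ...) {
  tibble::tibble(phi = x$phi, sigma = x$sigma, tau = x$tau,
                 logLik = x$logLik, n_obs = x$n_obs, method = x$method)
}

#' Variance-explained (R squared) of an AR1 fit
#'
#' The Gelman-style definition: variance of the fitted values over the
#' variance of fitted values plus residual variance. The interval comes from
#' a parametric bootstrap: new responses are simulated from the fitted model
#' (AR1 innovations, plus random intercepts at node level), the model is
#' refit, and the R squared distribution is summarized by percentiles.
#'
#' @param fit an `ar1_fit`.
#' @param n_boot parametric-bootstrap draws (default 200).
#' @param level interval level.
#' @param seed optional seed.
#' @return tibble `estimate`, `lower`, `upper`.
#' @export
r_squared <- function(fit, n_boot = 200, level = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  point <- r2_of(fit$fitted, fit$residuals)
  if (!is.finite(point)) stop("zero total variance: R squared undefined", call. = FALSE)
  draws <- vapply(seq_len(n_boot), function(b) {
    yb <- simulate_ar1_fit(fit)
    fb <- tryCatch(refit_ar1(fit, yb), error = function(e) NULL)
    if (is.null(fb)) return(NA_real_)
    r2_of(fb$fitted, fb$residuals)
  }, 1)
  draws <- draws[!is.na(draws)]
  q <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  tibble::tibble(estimate = point, lower = q[1], upper = q[2])
}

r2_of <- function(fitted, resid) {
  vf <- stats::var(fitted)
  vr <- stats::var(resid)
  if (vf + vr == 0) return(NA_real_)
  vf / (vf + vr)
}

simulate_ar1_fit <- function(fit) {
  beta <- fit$coefficients$estimate
  mu <- drop(fit$X %*% beta)
  if (fit$kind == "network") {
    n <- length(mu)
    e <- numeric(n)
    e[1] <- stats::rnorm(1, 0, fit$sigma / sqrt(1 - fit$phi^2))
    for (t in 2:n) e[t] <- fit$phi * e[t - 1] + stats::rnorm(1, 0, fit$sigma)
    mu + e
  } else {
    ids <- unique(fit$unit)
    b <- stats::setNames(stats::rnorm(length(ids), 0, fit$tau), ids)
    out <- mu + b[fit$unit]
    for (id in ids) {
      ix <- which(fit$unit == id)
      n_i <- length(ix)
      e <- numeric(n_i)
      e[1] <- stats::rnorm(1, 0, fit$sigma / sqrt(1 - fit$phi^2))
      if (n_i > 1) {
        for (t in 2:n_i) e[t] <- fit$phi * e[t - 1] + stats::rnorm(1, 0, fit$sigma)
      }
      out[ix] <- out[ix] + e
    }
    unname(out)
  }
}

refit_ar1 <- function(fit, y_new) {
  df <- tibble::as_tibble(as.data.frame(fit$X[, -1, drop = FALSE]))
  df$..y.. <- y_new
  if (fit$kind == "network") {
    fit_network_level(df, "..y..", predictors = colnames(fit$X)[-1],
                      ridge = fit$ridge, level = fit$level)
  } else {
    df$..unit.. <- fit$unit
    df$..t.. <- stats::ave(seq_len(nrow(df)), fit$unit, FUN = seq_along)
    fit_node_level(df, "..y..", predictors = colnames(fit$X)[-1],
                   unit = "..unit..", time = "..t..", level = fit$level)
  }
}

#' Export a model fit as JSON
#'
#' Mirrors the usual coefficient-table layout (term, estimate, error, lower
#' and upper CI) plus `phi`, `sigma`, `tau` and, when supplied, the R
#' squared summary. The error column is the ML standard error.
#'
#' @param fit an `ar1_fit`.
#' @param path output path.
#' @param r2 optional result of [r_squared()].
#' @export
write_fit <- function(fit, path, r2 = NULL) {
  co <- fit$coefficients
  jsonlite::write_json(list(
    kind = fit$kind, method = fit$method, n_obs = fit$n_obs,
    coefficients = lapply(seq_len(nrow(co)), function(i) list(
      term = co$term[i], estimate = co$estimate[i], error = co$std.error[i],
      lower = co$conf.low[i], upper = co$conf.high[i]
    )),
    phi = fit$phi, sigma = fit$sigma, tau = fit$tau,
    r_squared = if (!is.null(r2)) as.list(r2) else NULL
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
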