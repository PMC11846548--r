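#' @title ARIMA forecasting stage
#' @description
#' A deterministic ARIMA pipeline for short annual series: stationarity is
#' assessed with a KPSS test (ADF available as an option), the differencing
#' order d is the smallest one whose d-th difference passes, (p, q) are
#' chosen by an exhaustive AICc grid search, and the final model is fitted
#' by maximum likelihood with `stats::arima()`. Yearly frequency only; no
#' seasonal terms (20 annual observations cannot support them).
#' @name arima_stage
NULL

#' KPSS level-stationarity test statistic
#'
#' Null hypothesis: the series is level-stationary. The statistic is
#' `sum(S_t^2) / (n^2 * lrv)` where `S_t` are partial sums of the demeaned
#' series and `lrv` is the Bartlett-window long-run variance with
#' truncation `l = trunc(4 * (n/100)^0.25)` (the "short" lag convention).
#' Asymptotic 5% critical value for the level case: 0.463. A constant
#' series is reported as stationary (statistic 0).
#'
#' @param x numeric series.
#' @return List with `statistic` and `crit_5pct`.
#' @export
kpss_statistic <- function(x) {
  n <- length(x)
  e <- x - mean(x)
  if (sum(e^2) < 1e-12 * max(1, mean(x)^2)) {
    return(list(statistic = 0, crit_5pct = 0.463))
  }
  S <- cumsum(e)
  l <- trunc(4 * (n / 100)^0.25)
  s2 <- sum(e^2) / n
  if (l > 0) {
    for (h in seq_len(l)) {
      w <- 1 - h / (l + 1)
      s2 <- s2 + 2 * w * sum(e[(h + 1):n] * e[1:(n - h)]) / n
    }
  }
  s2 <- max(s2, .Machine$double.eps)
  list(statistic = sum(S^2) / (n^2 * s2), crit_5pct = 0.463)
}

#' Augmented Dickey-Fuller test statistic (constant, no trend)
#'
#' Null hypothesis: unit root. Regression of the first difference on a
#' constant, the lagged level and `k = trunc((n-1)^(1/3))` lagged
#' differences; the t-statistic on the lagged level is compared to the
#' asymptotic 5% critical value -2.86.
#'
#' @param x numeric series.
#' @return List with `statistic` (t on the lagged level) and `crit_5pct`.
#' @export
adf_statistic <- function(x) {
  n <- length(x)
  k <- trunc((n - 1)^(1 / 3))
  dx <- diff(x)
  if (stats::var(x) < 1e-12 * max(1, mean(x)^2)) {
    return(list(statistic = -Inf, crit_5pct = -2.86))  # constant: stationary
  }
  idx <- (k + 1):length(dx)
  X <- cbind(1, x[idx])                  # constant + lagged level
  if (k > 0) for (j in seq_len(k)) X <- cbind(X, dx[idx - j])
  yv <- dx[idx]
  fit <- stats::lm.fit(X, yv)
  res <- fit$residuals
  dof <- length(yv) - ncol(X)
  sigma2 <- sum(res^2) / dof
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  list(statistic = fit$coefficients[2] / se, crit_5pct = -2.86)
}

is_stationary <- function(x, test) {
  if (test == "kpss") {
    k <- kpss_statistic(x)
    k$statistic <= k$crit_5pct          # fail to reject stationarity
  } else {
    a <- adf_statistic(x)
    a$statistic < a$crit_5pct           # reject unit root
  }
}

#' Select the differencing order
#'
#' Returns the smallest `d <= max_d` whose d-th difference passes the
#' configured stationarity test at the 5% level. Reaching `max_d` without
#' passing is reported with a warning, not an error.
#'
#' @param series numeric series, length >= 10.
#' @param max_d maximum differencing order (default 2).
#' @param test `"kpss"` (default; null = stationary, the convention behind
#'   the usual `ndiffs` default) or `"adf"` (null = unit root).
#' @return Integer differencing order.
#' @export
select_difference_order <- function(series, max_d = 2, test = c("kpss", "adf")) {
  test <- match.arg(test)
  if (length(series) < 10) stop("series too short (need >= 10 points)", call. = FALSE)
  x <- as.numeric(series)
  for (d in 0:max_d) {
    if (is_stationary(x, test)) return(d)
    x <- diff(x)
  }
  warning(sprintf("series still non-stationary after %d differences; using d = %d",
                  max_d, max_d), call. = FALSE)
  max_d
}

arima_aicc <- function(fit, n_eff) {
  k <- length(fit$coef) + 1                # + innovation variance
  fit$aic + 2 * k * (k + 1) / max(n_eff - k - 1, 1e-8)
}

fit_one_arima <- function(series, p, d, q, include_constant, method = "CSS-ML") {
  n <- length(series)
  xreg <- NULL
  include_mean <- FALSE
  if (include_constant) {
    if (d == 0) include_mean <- TRUE
    if (d == 1) xreg <- matrix(seq_len(n), dimnames = list(NULL, "drift"))
  }
  tryCatch({
    fit <- suppressWarnings(stats::arima(series, order = c(p, d, q),
                                         include.mean = include_mean,
                                         xreg = xreg, method = method))
    # predict.Arima re-evaluates xreg from the stored call; embed the value
    # (assigning NULL drops the element when no regressor was used)
    fit$call$xreg <- xreg
    fit
  }, error = function(e) e)
}

#' Exhaustive (p, q) order search at fixed d
#'
#' Fits every ARIMA(p, d, q) with `p <= max_p`, `q <= max_q` by maximum
#' likelihood and returns the order with the smallest information
#' criterion (computed on the `n - d` effective observations); ties are
#' broken by smaller `p + q`, then smaller `p`. The search is fully
#' deterministic. A mean term is included for d = 0 and a drift regressor
#' for d = 1 (never a constant for d = 2), matching the usual
#' automatic-selection policy for annual series.
#'
#' BIC is the default criterion: it is order-consistent, whereas
#' AIC/AICc select overparameterised ARMA models with non-vanishing
#' probability even at large n (spurious near-unit-circle AR/MA pairs can
#' buy several log-likelihood points on an exhaustive grid), which is
#' fatal for order identification on a full (p, q) grid. AICc and AIC
#' remain available for users who prioritise one-step predictive loss
#' over identification.
#'
#' For long series (`n > 150`, the same threshold `auto.arima` uses) full
#' maximum likelihood over the whole grid is needlessly slow, so the grid
#' is first ranked by the conditional-sum-of-squares likelihood and only
#' the best `refit_top` candidates are refitted by full ML before the
#' final comparison; short annual series always use full ML throughout.
#' Both paths are deterministic.
#'
#' @param series numeric series.
#' @param d differencing order (e.g. from [select_difference_order()]).
#' @param max_p,max_q grid maxima (default 5).
#' @param criterion `"bic"` (default), `"aicc"` or `"aic"`.
#' @param approximation rank the grid by CSS before ML refitting; default
#'   `length(series) > 150`.
#' @param refit_top number of CSS-ranked candidates refitted by ML when
#'   `approximation` is on (default 8).
#' @return List of class `arima_order`: `p`, `d`, `q`, `criterion`,
#'   `value`, and `table` (ML-evaluated candidates).
#' @export
auto_select_order <- function(series, d, max_p = 5, max_q = 5,
                              criterion = c("bic", "aicc", "aic"),
                              approximation = length(series) > 150,
                              refit_top = 8) {
  criterion <- match.arg(criterion)
  n_eff <- length(series) - d
  crit_val <- function(fit) {
    k <- length(fit$coef) + 1
    switch(criterion,
           aicc = arima_aicc(fit, n_eff),
           aic = fit$aic,
           bic = fit$aic + k * (log(n_eff) - 2))
  }
  grid <- expand.grid(p = 0:max_p, q = 0:max_q)
  if (approximation) {
    css_val <- vapply(seq_len(nrow(grid)), function(i) {
      fit <- fit_one_arima(series, grid$p[i], d, grid$q[i],
                           include_constant = TRUE, method = "CSS")
      if (inherits(fit, "error")) return(Inf)
      k <- length(fit$coef) + 1
      # CSS log-likelihood stands in for the ML one during pre-ranking
      switch(criterion,
             aic = -2 * fit$loglik + 2 * k,
             aicc = -2 * fit$loglik + 2 * k + 2 * k * (k + 1) / max(n_eff - k - 1, 1e-8),
             bic = -2 * fit$loglik + k * log(n_eff))
    }, 0)
    keep <- order(css_val, grid$p + grid$q, grid$p)[seq_len(min(refit_top, nrow(grid)))]
    grid <- grid[keep, , drop = FALSE]
  }
  rows <- list()
  failures <- character(0)
  for (i in seq_len(nrow(grid))) {
    p <- grid$p[i]; q <- grid$q[i]
    fit <- fit_one_arima(series, p, d, q, include_constant = TRUE)
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("(%d,%d,%d): %s", p, d, q, conditionMessage(fit)))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(p = p, q = q, value = crit_val(fit))
  }
  if (!length(rows)) {
    stop("no ARIMA candidate converged:\n", paste(failures, collapse = "\n"),
         call. = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$value, tab$p + tab$q, tab$p), ]
  rownames(tab) <- NULL
  structure(list(p = tab$p[1], d = d, q = tab$q[1], criterion = criterion,
                 value = tab$value[1], table = tab),
            class = "arima_order")
}

#' Fit an ARIMA model and forecast
#'
#' Maximum-likelihood fit via `stats::arima()` with point forecasts and
#' normal-theory 95% intervals; a Ljung-Box residual summary is attached.
#' With `include_drift = TRUE` and d = 1 a linear-trend regressor is
#' included, so an ARIMA(0,1,0)-with-drift forecast is the exact linear
#' continuation `y_N + h * drift`.
#'
#' @param series numeric series.
#' @param order an `arima_order` or a length-3 vector `c(p, d, q)`.
#' @param horizon forecast steps (default 5).
#' @param include_drift include a constant/drift term: mean for d = 0,
#'   linear drift for d = 1 (default `TRUE`; ignored, with no constant,
#'   for d >= 2).
#' @param start_year optional calendar year of the first forecast step.
#' @param level interval coverage (default 0.95).
#' @return List of class `arima_forecast`: `order`, `coefficients`,
#'   `sigma2`, `aicc`, `ljung_box` (list: statistic, df, p_value) and
#'   `forecast`, a `forecast_series` data frame with `step`, optional
#'   `year`, `point`, `lower`, `upper`.
#' @export
fit_and_forecast <- function(series, order, horizon = 5,
                             include_drift = TRUE, start_year = NULL,
                             level = 0.95) {
  if (inherits(order, "arima_order")) order <- c(order$p, order$d, order$q)
  stopifnot(length(order) == 3, all(order >= 0))
  p <- order[1]; d <- order[2]; q <- order[3]
  n <- length(series)
  if (horizon < 1) stop("horizon must be >= 1", call. = FALSE)
  if (n <= p + q + d + 1) stop("series too short for the requested order", call. = FALSE)
  # degenerate case: the d-th difference is exactly constant (zero innovation
  # variance breaks the ML estimator) -> deterministic polynomial continuation
  # with zero-width intervals
  dx <- series
  if (d > 0) for (i in seq_len(d)) dx <- diff(dx)
  if (stats::var(dx) < 1e-20 * max(1, mean(abs(series)))^2) {
    yy <- series
    pt <- numeric(horizon)
    for (h in seq_len(horizon)) {
      nxt <- if (d == 0) mean(dx) else {
        # continue by re-integrating the constant d-th difference
        tailvals <- utils::tail(yy, d)
        sum(vapply(0:(d - 1), function(j) choose(d, j + 1) * (-1)^j *
                     tailvals[d - j], 0)) + dx[1] * (d > 0)
      }
      pt[h] <- nxt
      yy <- c(yy, nxt)
    }
    fc <- data.frame(step = seq_len(horizon), point = pt, lower = pt, upper = pt)
    if (!is.null(start_year)) fc$year <- start_year + fc$step - 1L
    class(fc) <- c("forecast_series", "data.frame")
    return(structure(list(order = c(p = p, d = d, q = q),
                          coefficients = c(mean = mean(series)), sigma2 = 0,
                          aicc = -Inf, ljung_box = NULL, forecast = fc,
                          model = NULL),
                     class = "arima_forecast"))
  }
  fit <- fit_one_arima(series, p, d, q, include_constant = include_drift)
  if (inherits(fit, "error")) {
    stop("ARIMA fit failed: ", conditionMessage(fit), call. = FALSE)
  }
  newxreg <- if (include_drift && d == 1) {
    matrix(n + seq_len(horizon), dimnames = list(NULL, "drift"))
  } else NULL
  pr <- stats::predict(fit, n.ahead = horizon, newxreg = newxreg)
  z <- stats::qnorm(1 - (1 - level) / 2)
  fc <- data.frame(step = seq_len(horizon),
                   point = as.numeric(pr$pred),
                   lower = as.numeric(pr$pred - z * pr$se),
                   upper = as.numeric(pr$pred + z * pr$se))
  if (!is.null(start_year)) fc$year <- start_year + fc$step - 1L
  class(fc) <- c("forecast_series", "data.frame")
  lb_lag <- min(10, max(1, floor(length(series) / 5)))
  lb <- tryCatch(stats::Box.test(stats::residuals(fit), lag = lb_lag,
                                 type = "Ljung-Box", fitdf = min(p + q, lb_lag - 1)),
                 error = function(e) NULL)
  structure(list(order = c(p = p, d = d, q = q),
                 coefficients = stats::coef(fit), sigma2 = fit$sigma2,
                 aicc = arima_aicc(fit, n - d),
                 ljung_box = if (is.null(lb)) NULL else
                   list(statistic = unname(lb$statistic), df = unname(lb$parameter),
                        p_value = unname(lb$p.value)),
                 forecast = fc, model = fit),
            class = "arima_forecast")
}

#' @export
print.arima_order <- function(x, ...) {
  cat(sprintf("ARIMA order (%d,%d,%d) selected by %s = %.2f\n",
              x$p, x$d, x$q, toupper(x$criterion), x$value))
  invisible(x)
}

#' @export
print.arima_forecast <- function(x, ...) {
  cat(sprintf("ARIMA(%d,%d,%d) fit, AICc = %.2f\n",
              x$order["p"], x$order["d"], x$order["q"], x$aicc))
  print(as.data.frame(x$forecast))
  invisible(x)
}
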