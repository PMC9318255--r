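#' Baranyi-Roberts growth curve on the log10 scale
#'
#' Mean function of the Baranyi-Roberts model for microbial growth under
#' constant conditions. Public parameters follow the plate-count convention:
#' levels in log10 CFU/g and the maximum specific rate in log10 units per
#' day. Internally the curve is evaluated in natural-log units
#' (`x = y ln 10`, `mu = mu_max ln 10`):
#'
#'   x(t) = x0 + mu A(t) - ln(1 + (exp(mu A(t)) - 1) / exp(xmax - x0))
#'   A(t) = t + (1/mu) ln(exp(-mu t) + exp(-h0) - exp(-mu t - h0))
#'
#' with the dimensionless initial physiological state `h0 = mu * lag`, so the
#' lag phase is `lag = h0 / mu` days and `h0 = 0` means no lag.
#'
#' @param t time, days (vector, >= 0).
#' @param y0 initial level, log10 CFU/g.
#' @param mu_max maximum specific growth rate, log10 CFU/g per day (> 0).
#' @param ymax asymptotic level, log10 CFU/g (> y0).
#' @param lag lag-phase duration, days (>= 0; default 0).
#' @return log10 CFU/g at each `t`; `y(0) = y0`, nondecreasing, sup = `ymax`.
#' @export
baranyi_log10 <- function(t, y0, mu_max, ymax, lag = 0) {
  if (any(t < 0)) stop("t must be nonnegative")
  if (mu_max <= 0) stop("mu_max must be positive")
  if (ymax <= y0) stop("ymax must exceed y0")
  if (lag < 0) stop("lag must be nonnegative")
  ln10 <- log(10)
  mu <- mu_max * ln10
  x0 <- y0 * ln10
  xmax <- ymax * ln10
  h0 <- mu * lag
  # A(t) via log1p-stable form; exp(-h0) - exp(-mu t - h0) = exp(-h0)(1 - exp(-mu t))
  A <- t + (1 / mu) * log(exp(-mu * t) + exp(-h0) * (1 - exp(-mu * t)))
  muA <- mu * A
  x <- x0 + muA - log1p(expm1(muA) * exp(-(xmax - x0)))
  x / ln10
}

#' Fit the Baranyi-Roberts model to a growth curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) on log10 counts, pooling all supplied points into one
#' residual vector. Four deterministic initializations derived from the data
#' (rate and lag heuristics varied) are tried and the best SSE kept. The
#' no-lag variant fixes `h0 = 0` (i.e. `lag = 0`); `with_lag = "auto"` fits
#' both and retains the lag only when it exceeds 0.1 d and improves the fit
#' at the 5% level by an extra-sum-of-squares F test (nested models).
#'
#' @param times sampling days (vector).
#' @param log10_counts observed log10 CFU/g, same length as `times`.
#' @param with_lag `TRUE`, `FALSE`, or `"auto"` (default).
#' @return object of class `baranyi_fit`: list with `params` (y0, mu_max,
#'   ymax, lag, h0), `sse`, `r_squared`, `with_lag`, `fitted`, and for
#'   `"auto"` the comparison p-value `lag_test_p`.
#' @export
fit_baranyi <- function(times, log10_counts, with_lag = "auto") {
  ok <- is.finite(times) & is.finite(log10_counts)
  t <- times[ok]; y <- log10_counts[ok]
  if (length(t) < 5L) stop("need at least 5 points spanning growth")
  if (stats::sd(y) == 0) stop("constant counts: no growth signal to fit")
  if (identical(with_lag, "auto")) {
    f0 <- fit_baranyi(times, log10_counts, with_lag = FALSE)
    f1 <- fit_baranyi(times, log10_counts, with_lag = TRUE)
    n <- length(t)
    # extra-sum-of-squares F test, 1 extra parameter (lag)
    df2 <- n - 4L
    p <- if (f1$sse <= .Machine$double.eps * n || df2 < 1L) 0 else
      stats::pf((f0$sse - f1$sse) / (f1$sse / df2), 1, df2, lower.tail = FALSE)
    keep <- f1$params[["lag"]] >= 0.1 && p < 0.05 && f1$sse <= f0$sse
    out <- if (keep) f1 else f0
    out$lag_test_p <- p
    return(out)
  }
  free_lag <- isTRUE(with_lag)
  n_par <- if (free_lag) 4L else 3L
  if (length(t) <= n_par) stop("fewer points than free parameters")
  tmax <- max(t)
  # data-driven heuristics: steepest successive slope and its backward
  # intersection with the initial level give rate and lag starting values
  o <- order(t); ts <- t[o]; ys <- y[o]
  dy <- diff(ys); dt <- diff(ts)
  sl <- ifelse(dt > 0, dy / dt, 0)
  i <- which.max(sl)
  mu_hat <- max(sl[i], 0.1)
  lag_hat <- max(0, ts[i] - (ys[i] - min(ys)) / mu_hat)
  starts <- list(
    c(y0 = min(ys), mu_max = mu_hat, ymax = max(ys), lag = lag_hat),
    c(y0 = min(ys), mu_max = mu_hat / 2, ymax = max(ys), lag = 0),
    c(y0 = min(ys), mu_max = min(2 * mu_hat, 5), ymax = max(ys) + 0.5,
      lag = min(lag_hat + 1, tmax)),
    c(y0 = ys[1], mu_max = 1, ymax = max(ys), lag = tmax / 4)
  )
  lower <- c(y0 = 0, mu_max = 1e-6, ymax = 0, lag = 0)
  upper <- c(y0 = 12, mu_max = 5, ymax = 12, lag = tmax)
  resid_fn <- function(p) {
    y0 <- p[["y0"]]; mu <- p[["mu_max"]]
    ymax <- max(p[["ymax"]], y0 + 1e-6)
    lag <- if (free_lag) p[["lag"]] else 0
    y - baranyi_log10(t, y0, mu, ymax, lag)
  }
  best <- NULL
  for (st in starts) {
    par0 <- if (free_lag) st else st[c("y0", "mu_max", "ymax")]
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = pmin(pmax(par0, lower[names(par0)]), upper[names(par0)]),
        lower = lower[names(par0)], upper = upper[names(par0)],
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                             maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("Baranyi fit failed to converge from all starts")
  cf <- stats::coef(best$fit)
  lag <- if (free_lag) unname(cf[["lag"]]) else 0
  params <- list(y0 = unname(cf[["y0"]]), mu_max = unname(cf[["mu_max"]]),
                 ymax = unname(cf[["ymax"]]), lag = lag,
                 h0 = unname(cf[["mu_max"]]) * log(10) * lag)
  fitted <- baranyi_log10(t, params$y0, params$mu_max, params$ymax, params$lag)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(params = params, sse = best$sse,
         r_squared = 1 - best$sse / ss_tot,
         with_lag = free_lag, times = t, observed = y, fitted = fitted),
    class = "baranyi_fit"
  )
}

#' Correlation between QI and microbial counts across storage days
#'
#' Pearson correlation of day-mean QI with day-mean log10 counts on matched
#' days, with the p-value from the simple linear regression F test
#' (1 and n-2 degrees of freedom).
#'
#' @param qi_series data.frame with `storage_day` and `mean_qi` (e.g. from
#'   [aggregate_qi()]).
#' @param count_series data.frame with `storage_day` and `mean_log10` columns
#'   (day means of log10 CFU/g).
#' @return list with `r`, `p_r`, `n` (matched days).
#' @export
qi_count_correlation <- function(qi_series, count_series) {
  m <- merge(qi_series[, c("storage_day", "mean_qi")],
             count_series[, c("storage_day", "mean_log10")],
             by = "storage_day")
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 matched storage days")
  if (stats::sd(m$mean_qi) == 0 || stats::sd(m$mean_log10) == 0)
    stop("zero variance in one of the series")
  r <- stats::cor(m$mean_qi, m$mean_log10)
  Fstat <- r^2 * (n - 2) / (1 - r^2)
  p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  list(r = r, p_r = p, n = n)
}

#' Day means of a long plate-count table
#'
#' @param counts data.frame with `storage_day` and `log10_cfu_g` columns
#'   (replicates pooled).
#' @return data.frame with `storage_day`, `mean_log10`, `n`.
#' @export
aggregate_counts <- function(counts) {
  if (!all(c("storage_day", "log10_cfu_g") %in% names(counts)))
    stop("counts must have storage_day and log10_cfu_g columns")
  agg <- stats::aggregate(log10_cfu_g ~ storage_day, data = counts,
                          FUN = mean)
  n <- stats::aggregate(log10_cfu_g ~ storage_day, data = counts,
                        FUN = length)
  data.frame(storage_day = agg$storage_day, mean_log10 = agg$log10_cfu_g,
             n = n$log10_cfu_g)
}
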