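#' Tetrad proportion correct as a function of d-prime
#'
#' Psychometric function of the unidimensional, equal-variance Thurstonian
#' model for the tetrad protocol. Each assessor receives two samples from
#' N(0,1) and two from N(delta,1) and groups the four into two pairs; under
#' the optimal decision rule the grouping is by sorted adjacency (the two
#' smallest percepts paired together), so a response is correct when both
#' samples of one product fall below both samples of the other. This gives
#'
#'   Pc(delta) = int 2 phi(x) Phi(x) \[ (1-Phi(x-delta))^2 + (1-Phi(x+delta))^2 \] dx
#'
#' evaluated by adaptive quadrature. Chance level is exactly 1/3.
#'
#' @param dprime sensory distance in perceptual standard-deviation units
#'   (scalar or vector, >= 0).
#' @return proportion correct in `[1/3, 1)`, strictly increasing in `dprime`.
#' @export
tetrad_pc <- function(dprime) {
  if (any(dprime < 0)) stop("dprime must be nonnegative")
  vapply(dprime, function(d) {
    if (d == 0) return(1 / 3)
    stats::integrate(function(x) {
      2 * stats::dnorm(x) * stats::pnorm(x) *
        ((1 - stats::pnorm(x - d))^2 + (1 - stats::pnorm(x + d))^2)
    }, -Inf, Inf, rel.tol = 1e-11, abs.tol = 1e-11)$value
  }, numeric(1))
}

#' Exact binomial tetrad difference test
#'
#' Tests H0: no perceivable difference (proportion correct = 1/3) against the
#' one-sided alternative of above-chance grouping. The p-value is the exact
#' upper binomial tail, summed term by term; no normal approximation is used.
#'
#' @param n_assessors number of assessors (trials).
#' @param n_correct number of correct groupings.
#' @return list with `p_value`, `proportion_correct`, `n_assessors`,
#'   `n_correct`.
#' @export
tetrad_difference_test <- function(n_assessors, n_correct) {
  check_tetrad_counts(n_assessors, n_correct)
  p <- sum(stats::dbinom(n_correct:n_assessors, n_assessors, 1 / 3))
  list(p_value = min(1, p),
       proportion_correct = n_correct / n_assessors,
       n_assessors = n_assessors, n_correct = n_correct)
}

#' Exact binomial tetrad similarity test
#'
#' Tests H0: the sensory distance is at least `dprime0` against the
#' alternative of a smaller difference; similarity is declared when the
#' correct count is improbably low under Pc(dprime0). The p-value is the
#' exact lower binomial tail at `tetrad_pc(dprime0)`; the reported
#' `confidence` is 1 - p.
#'
#' @inheritParams tetrad_difference_test
#' @param dprime0 the similarity margin d'0 (> 0) the test rules out.
#' @return list with `p_value`, `confidence`, `pc0` (proportion correct under
#'   the margin), plus the inputs.
#' @export
tetrad_similarity_test <- function(n_assessors, n_correct, dprime0) {
  check_tetrad_counts(n_assessors, n_correct)
  if (dprime0 <= 0)
    stop("dprime0 must be positive: the similarity null is degenerate at 0")
  pc0 <- tetrad_pc(dprime0)
  p <- sum(stats::dbinom(0:n_correct, n_assessors, pc0))
  p <- min(1, p)
  list(p_value = p, confidence = 1 - p, pc0 = pc0, dprime0 = dprime0,
       n_assessors = n_assessors, n_correct = n_correct)
}

#' Sample-size planning for a tetrad similarity test
#'
#' For each candidate panel size n, the critical value c(n) is the largest
#' correct count whose lower-tail probability under Pc(dprime0) stays within
#' alpha; the power is the probability of observing at most c(n) correct
#' responses when the products are in fact identical (proportion correct 1/3).
#' Returns the smallest n whose power reaches the target. Exact binomial
#' probabilities throughout.
#'
#' @param dprime0 similarity margin d'0 (> 0).
#' @param alpha significance level of the similarity test.
#' @param target_power required power under the identity alternative.
#' @param n_max largest panel size searched (default 10000).
#' @return list with `n` (minimum panel size), `critical_value`, `power`
#'   (achieved), `pc0`, and a `search` data.frame (n, critical value, power)
#'   over the searched range up to the solution.
#' @export
tetrad_sample_size <- function(dprime0, alpha, target_power, n_max = 10000L) {
  if (dprime0 <= 0) stop("dprime0 must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (target_power <= 0 || target_power >= 1) stop("target_power must be in (0,1)")
  pc0 <- tetrad_pc(dprime0)
  rows <- vector("list", 0L)
  for (n in seq_len(n_max)) {
    # largest c with P(X <= c | n, pc0) <= alpha (may be absent for small n)
    cv <- stats::qbinom(alpha, n, pc0) # first c with CDF > alpha is cv or cv+1
    while (cv >= 0 && stats::pbinom(cv, n, pc0) > alpha) cv <- cv - 1L
    pow <- if (cv < 0) 0 else stats::pbinom(cv, n, 1 / 3)
    rows[[length(rows) + 1L]] <- data.frame(n = n, critical_value = cv,
                                            power = pow)
    if (pow >= target_power) {
      return(list(n = n, critical_value = cv, power = pow, pc0 = pc0,
                  search = do.call(rbind, rows)))
    }
  }
  stop("target power unreachable within n <= ", n_max)
}

#' Thurstonian d-prime estimate from tetrad counts
#'
#' Inverts the tetrad psychometric function at the observed proportion
#' correct by bisection on `[0, 15]` (tolerance 1e-8). Proportions at or
#' below chance map to 0. A perfect score is capped at the d' giving
#' Pc = 1 - 1/(2n) and flagged as saturated. The standard error follows from
#' the delta method, `se = sqrt(p(1-p)/n) / Pc'(d)`, with the derivative by
#' central difference.
#'
#' @inheritParams tetrad_difference_test
#' @return list with `dprime`, `se`, `proportion_correct`, `saturated`.
#' @export
estimate_dprime <- function(n_assessors, n_correct) {
  check_tetrad_counts(n_assessors, n_correct)
  phat <- n_correct / n_assessors
  saturated <- FALSE
  if (phat <= 1 / 3) {
    d <- 0
  } else {
    target <- phat
    if (n_correct == n_assessors) {
      target <- 1 - 1 / (2 * n_assessors)
      saturated <- TRUE
    }
    lo <- 0; hi <- 15
    while (hi - lo > 1e-8) {
      mid <- (lo + hi) / 2
      if (tetrad_pc(mid) < target) lo <- mid else hi <- mid
    }
    d <- (lo + hi) / 2
  }
  h <- 1e-4
  dpc <- (tetrad_pc(d + h) - tetrad_pc(max(0, d - h))) / (h + min(d, h))
  se <- if (dpc > 0) sqrt(phat * (1 - phat) / n_assessors) / dpc else Inf
  list(dprime = d, se = se, proportion_correct = phat, saturated = saturated)
}

check_tetrad_counts <- function(n_assessors, n_correct) {
  if (length(n_assessors) != 1L || n_assessors < 1 || n_assessors != round(n_assessors))
    stop("n_assessors must be a positive integer")
  if (n_correct < 0 || n_correct > n_assessors || n_correct != round(n_correct))
    stop("n_correct must be an integer in [0, n_assessors]")
  invisible(TRUE)
}
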