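# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Ordinary least squares by the closed-form normal equations.
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Textbook sums-of-squares decomposition for a balanced two-way layout with
# interaction and replication. `d` has columns y, A, B.
anova_ss_oracle <- function(d) {
  grand <- mean(d$y)
  cell <- tapply(d$y, list(d$A, d$B), mean)
  ma <- tapply(d$y, d$A, mean)
  mb <- tapply(d$y, d$B, mean)
  a <- nlevels(factor(d$A)); b <- nlevels(factor(d$B))
  r <- nrow(d) / (a * b)
  ss_a <- b * r * sum((ma - grand)^2)
  ss_b <- a * r * sum((mb - grand)^2)
  ss_ab <- r * sum(sweep(sweep(cell, 1, ma), 2, mb)^2) + r * a * b * grand^2 -
    r * sum(cell^2) + r * sum(cell^2) # expanded below for clarity
  ss_ab <- r * sum((cell - outer(ma, rep(1, b)) - outer(rep(1, a), mb) + grand)^2)
  pred <- cell[cbind(as.integer(factor(d$A)), as.integer(factor(d$B)))]
  ss_e <- sum((d$y - pred)^2)
  df <- c(a - 1, b - 1, (a - 1) * (b - 1), nrow(d) - a * b)
  ms <- c(ss_a, ss_b, ss_ab) / df[1:3]
  mse <- ss_e / df[4]
  list(ss = c(A = ss_a, B = ss_b, AB = ss_ab, E = ss_e), df = df,
       F = ms / mse,
       p = stats::pf(ms / mse, df[1:3], df[4], lower.tail = FALSE))
}

# Monte-Carlo tetrad simulation with the sorted-adjacency grouping rule,
# chunked to bound memory. Returns the empirical proportion correct.
mc_tetrad_pc <- function(dprime, reps, seed, chunk = 2.5e6) {
  set.seed(seed)
  hits <- 0
  left <- reps
  while (left > 0) {
    m <- min(chunk, left)
    a1 <- rnorm(m); a2 <- rnorm(m)
    b1 <- rnorm(m, dprime); b2 <- rnorm(m, dprime)
    hits <- hits + sum(pmax(a1, a2) < pmin(b1, b2) |
                         pmax(b1, b2) < pmin(a1, a2))
    left <- left - m
  }
  hits / reps
}

# Balanced DA dataset built directly (not via gen_da) for ANOVA cross-checks.
make_balanced_da <- function(cell_means, n_assessors, replicates, sd, seed,
                             attribute = "attr") {
  set.seed(seed)
  samples <- rownames(cell_means)
  trt <- ifelse(substr(samples, 1, 1) == "C", "Control", "SUSEA")
  day <- as.integer(sub("^[CS]D", "", samples))
  g <- expand.grid(assessor = seq_len(n_assessors),
                   replicate = seq_len(replicates),
                   sample = seq_along(samples))
  data.frame(
    assessor_id = sprintf("P%02d", g$assessor),
    treatment = trt[g$sample],
    storage_day = day[g$sample],
    replicate = g$replicate,
    attribute = attribute,
    intensity = cell_means[g$sample, 1] + rnorm(nrow(g), 0, sd))
}

cells6 <- function(values) {
  matrix(values, nrow = 6, dimnames = list(c("CD1", "CD5", "CD7",
                                             "SD1", "SD5", "SD7"), NULL))
}
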