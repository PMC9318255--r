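scheme <- seabream_fillet_scheme()

test_that("total QI sums demerit points and respects the score space", {
  attrs <- names(scheme$max_demerit)
  zeros <- setNames(rep(0L, 6), attrs)
  expect_identical(total_qi(zeros, scheme), 0L)
  maxed <- setNames(c(2L, 2L, 2L, 3L, 2L, 2L), attrs)
  expect_identical(total_qi(maxed, scheme), 13L)
  mixed <- setNames(c(1L, 1L, 0L, 2L, 1L, 0L), attrs)
  expect_identical(total_qi(mixed, scheme), 5L)
  expect_error(total_qi(zeros[-1], scheme), "missing attribute")
  bad <- zeros; bad[["odor"]] <- 4L
  expect_error(total_qi(bad, scheme), "out of demerit range")
})

test_that("total QI is monotone nondecreasing in every attribute score", {
  attrs <- names(scheme$max_demerit)
  set.seed(42)
  for (i in 1:25) {
    s <- setNames(vapply(scheme$max_demerit, function(m) sample(0:m, 1),
                         integer(1)), attrs)
    base <- total_qi(s, scheme)
    for (a in attrs) {
      if (s[[a]] < scheme$max_demerit[[a]]) {
        s2 <- s; s2[[a]] <- s2[[a]] + 1L
        expect_gte(total_qi(s2, scheme), base)
      }
    }
  }
})

test_that("scheme validation reports the score space and rejects malformed schemes", {
  v <- validate_scheme(scheme)
  expect_equal(v$max_qi, 13)
  expect_equal(v$n_attributes, 6)
  gap <- data.frame(modality = "Odor", attribute = "odor",
                    demerit = c(0, 2), description = c("fresh", "off"))
  expect_error(qim_scheme(gap), "consecutive")
  single <- data.frame(modality = "Odor", attribute = "odor",
                       demerit = 0:3, description = letters[1:4])
  expect_equal(qim_scheme(single)$max_qi, 3)
  expect_error(qim_scheme(single[0, ]), "empty")
})

make_evals <- function(day, qis, acceptable = rep(1L, length(qis))) {
  rows <- lapply(seq_along(qis), function(i) {
    qi <- qis[i]
    alloc <- integer(6); names(alloc) <- names(scheme$max_demerit)
    left <- qi
    for (a in names(alloc)) {
      alloc[[a]] <- min(left, scheme$max_demerit[[a]]); left <- left - alloc[[a]]
    }
    data.frame(storage_day = day[min(i, length(day))],
               assessor_id = paste0("J", i), fillet_id = paste0("F", i),
               treatment = "Control", t(alloc), acceptable = acceptable[i])
  })
  do.call(rbind, rows)
}

test_that("aggregation averages per-day QI over all available records", {
  one <- make_evals(1, 4)
  s <- aggregate_qi(one, scheme)
  expect_equal(s$mean_qi, 4)
  expect_equal(s$n, 1L)
  two <- make_evals(c(1, 1), c(4, 6))
  expect_equal(aggregate_qi(two, scheme)$mean_qi, 5)
  expect_error(aggregate_qi(two[0, ], scheme), "no evaluations")
})

test_that("trend fit matches the closed-form least-squares oracle", {
  days <- c(1, 5, 7, 8, 11)
  series <- data.frame(storage_day = days,
                       mean_qi = 0.7318 * days + 0.8183)
  fit <- fit_qi_trend(series)
  expect_equal(fit$slope, 0.7318, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.8183, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  two <- data.frame(storage_day = c(2, 6), mean_qi = c(1, 9))
  f2 <- fit_qi_trend(two)
  expect_equal(f2$slope, 2)
  expect_equal(f2$r_squared, 1)

  set.seed(7)
  x <- sort(sample(0:14, 6)); y <- runif(6, 0, 13)
  f3 <- fit_qi_trend(data.frame(storage_day = x, mean_qi = y))
  o <- ols_oracle(x, y)
  expect_equal(f3$slope, o$slope, tolerance = 1e-10)
  expect_equal(f3$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(f3$r_squared, o$r_squared, tolerance = 1e-10)

  expect_error(fit_qi_trend(data.frame(storage_day = 1, mean_qi = 3)),
               "at least 2 distinct")
})

test_that("rejection QI is the minimum QI judged unacceptable", {
  e1 <- make_evals(c(5, 7), c(4, 6), acceptable = c(1L, 0L))
  expect_equal(rejection_threshold(e1, scheme), 6)
  e2 <- make_evals(c(5, 7, 8), c(8, 3, 5), acceptable = c(0L, 0L, 1L))
  expect_equal(rejection_threshold(e2, scheme), 3)
  e3 <- make_evals(c(5, 7), c(4, 6))
  expect_error(rejection_threshold(e3, scheme), "undeterminable")
})

test_that("shelf life floors the threshold crossing time", {
  c1 <- shelf_life_days(list(slope = 0.7318, intercept = 0.8183), 6)
  expect_equal(c1$crossing_time, 7.0808, tolerance = 1e-4)
  expect_identical(c1$shelf_life_days, 7L)
  c2 <- shelf_life_days(list(slope = 0.5655, intercept = 0.8839), 6)
  expect_equal(c2$crossing_time, 9.047, tolerance = 1e-3)
  expect_identical(c2$shelf_life_days, 9L)
  c3 <- shelf_life_days(list(slope = 1, intercept = 0), 5)
  expect_identical(c3$shelf_life_days, 5L)
  expect_error(shelf_life_days(list(slope = -0.1, intercept = 1), 6),
               "non-positive slope")
  expect_error(shelf_life_days(list(slope = 0.5, intercept = 7), 6),
               "below the fitted intercept")
})

test_that("shelf life is monotone in slope and threshold", {
  slopes <- seq(0.3, 1.5, by = 0.1)
  days_by_slope <- vapply(slopes, function(s)
    shelf_life_days(list(slope = s, intercept = 0.8), 6)$shelf_life_days,
    integer(1))
  expect_true(all(diff(days_by_slope) <= 0))
  thresholds <- 1:12
  days_by_thr <- vapply(thresholds, function(q)
    shelf_life_days(list(slope = 0.7, intercept = 0.5), q)$shelf_life_days,
    integer(1))
  expect_true(all(diff(days_by_thr) >= 0))
})

test_that("percent extension rounds half-up to whole percent", {
  expect_identical(extension_percent(7, 9), 29L)
  expect_identical(extension_percent(7, 7), 0L)
  expect_identical(extension_percent(7, 14), 100L)
  expect_identical(extension_percent(8, 9), 13L) # 12.5 rounds up
  expect_error(extension_percent(0, 9), "positive")
})
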