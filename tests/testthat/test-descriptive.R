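test_that("two-way ANOVA matches the textbook SS decomposition on balanced data", {
  set.seed(21)
  for (rep in 1:5) {
    cm <- cells6(rnorm(6, 6, 2))
    d <- make_balanced_da(cm, n_assessors = 6, replicates = 2, sd = 1,
                          seed = 500 + rep)
    res <- da_anova(d, "attr", drop_interaction_p = 1.01) # keep interaction
    o <- anova_ss_oracle(data.frame(y = d$intensity, A = d$treatment,
                                    B = d$storage_day))
    tab <- res$table
    expect_equal(tab$ss[tab$term == "treatment"], unname(o$ss["A"]),
                 tolerance = 1e-10)
    expect_equal(tab$ss[tab$term == "day"], unname(o$ss["B"]),
                 tolerance = 1e-10)
    expect_equal(tab$ss[tab$term == "interaction"], unname(o$ss["AB"]),
                 tolerance = 1e-10)
    expect_equal(tab$statistic[tab$term == "treatment"], unname(o$F[1]),
                 tolerance = 1e-10)
    expect_equal(tab$statistic[tab$term == "interaction"], unname(o$F[3]),
                 tolerance = 1e-10)
    # SS additivity under balance
    total <- sum((d$intensity - mean(d$intensity))^2)
    expect_equal(sum(tab$ss), total, tolerance = 1e-8 * total)
  }
})

test_that("zero-noise data with no effects yields zero factor SS", {
  d <- make_balanced_da(cells6(rep(7, 6)), 4, 2, sd = 0, seed = 1)
  res <- da_anova(d, "attr")
  expect_false(res$interaction_retained)
  ss <- res$table$ss[res$table$term != "residual"]
  expect_true(all(abs(ss) < 1e-18))
})

test_that("interaction elimination follows the p < 0.1 rule", {
  # additive truth: interaction dropped
  add <- cells6(c(5, 6, 7, 6, 7, 8))
  d1 <- make_balanced_da(add, 10, 3, sd = 1, seed = 9)
  r1 <- da_anova(d1, "attr")
  expect_false(r1$interaction_retained)
  expect_false("interaction" %in% r1$table$term)
  # crossing color-intensity pattern: interaction retained
  color <- cells6(c(5.52, 5.80, 7.88, 5.19, 8.02, 6.87))
  d2 <- make_balanced_da(color, 10, 3, sd = 1, seed = 10)
  r2 <- da_anova(d2, "attr")
  expect_true(r2$interaction_retained)
  expect_lt(r2$table$p[r2$table$term == "interaction"], 0.05)
})

test_that("LSD letters reproduce pairwise t-test significance exactly", {
  # identical means share one letter
  d0 <- make_balanced_da(cells6(rep(6, 6)), 6, 2, sd = 0.5, seed = 31)
  r0 <- da_anova(d0, "attr")
  g0 <- fisher_lsd(r0, "treatment")
  expect_true(all(g0$letters == g0$letters[1]))
  # widely separated treatments get distinct letters, 'a' on the higher mean
  dwide <- make_balanced_da(cells6(c(2, 2, 2, 12, 12, 12)), 6, 2, 0.5, 32)
  gw <- fisher_lsd(da_anova(dwide, "attr"), "treatment")
  expect_identical(gw$letters, c("a", "b"))
  expect_identical(gw$level[1], "SUSEA")
  # umami-style calibration: treated higher, within-treatment days equal
  umami <- cells6(c(5.73, 5.32, 4.19, 7.34, 7.59, 7.27))
  gu <- fisher_lsd(da_anova(make_balanced_da(umami, 10, 3, 1, 33), "attr"),
                   "treatment")
  expect_identical(gu$level, c("SUSEA", "Control"))
  expect_identical(gu$letters, c("a", "b"))
  # random instances: letter sharing iff pairwise t nonsignificant
  for (s in 1:8) {
    cm <- cells6(runif(6, 3, 9))
    d <- make_balanced_da(cm, 5, 2, sd = 1, seed = 600 + s)
    res <- da_anova(d, "attr", drop_interaction_p = 1.01)
    g <- fisher_lsd(res, "cell", alpha = 0.05)
    pmat <- attr(g, "pairwise")
    for (i in 1:5) for (j in (i + 1):6) {
      share <- any(strsplit(g$letters[i], "")[[1]] %in%
                     strsplit(g$letters[j], "")[[1]])
      expect_identical(share, pmat[i, j] >= 0.05,
                       label = sprintf("seed %d pair %d-%d", s, i, j))
    }
  }
})

test_that("covariance PCA explains variance correctly and projects supplementary rows", {
  # rank-1 matrix: first component carries everything
  v <- outer(c(1, 2, 3, 4), c(2, -1, 0.5, 1, 3))
  p1 <- pca_covariance(v)
  expect_equal(sum(p1$explained), 1, tolerance = 1e-12)
  expect_equal(p1$explained[1], 1, tolerance = 1e-12)
  # supplementary row duplicating an active row scores identically
  cm <- da_cell_means()$cells
  marg <- marginal_profiles(cm)
  p2 <- pca_covariance(marg, supplementary = marg[c("Control", "D7"), ])
  expect_equal(p2$supplementary_scores["Control", ],
               p2$scores["Control", ], tolerance = 1e-10)
  expect_equal(sum(p2$explained), 1, tolerance = 1e-12)
  expect_error(pca_covariance(marg[1, , drop = FALSE]), "at least 2")
})

test_that("Varimax preserves the variance of the rotated subspace", {
  cm <- da_cell_means()$cells
  marg <- marginal_profiles(cm)
  p <- pca_covariance(marg, supplementary = cm, rotate = TRUE, k = 2)
  pre <- sum(p$explained[1:2])
  post <- sum(p$rotated$explained)
  expect_equal(post, pre, tolerance = 1e-10)
  # rotated axes stay orthonormal, so scores are a rigid rotation
  expect_equal(unname(crossprod(p$rotated$axes)), diag(2), tolerance = 1e-10)
})

test_that("bootstrap hulls are seeded, contain the sample mean, and collapse without variance", {
  cm <- da_cell_means()$cells[, 1:8]
  da <- gen_da(cm, sd_assessor = 0.8, sd_replicate = 1, n_assessors = 8,
               replicates = 2, seed = 5)
  marg <- marginal_profiles(empirical_cell_means(da, colnames(cm)))
  model <- pca_covariance(marg, rotate = FALSE)
  h1 <- bootstrap_hulls(da, model, B = 40, seed = 17)
  h2 <- bootstrap_hulls(da, model, B = 40, seed = 17)
  expect_identical(h1, h2)
  # each hull contains (or touches) the full-data projected sample mean:
  # adding the mean to the cloud must not create a new exterior vertex
  cells <- empirical_cell_means(da, colnames(cm))
  proj <- sweep(cells, 2, model$center) %*% model$axes[, 1:2]
  for (s in rownames(cells)) {
    key <- paste0(ifelse(substr(s, 1, 1) == "C", "Control", "SUSEA"),
                  ":", sub("^[CS]D", "", s))
    hull <- h1[[key]]
    expect_false(hull$degenerate)
    aug <- rbind(hull$points, proj[s, ])
    verts <- grDevices::chull(aug)
    strictly_outside <- (nrow(aug) %in% verts) &&
      !any(apply(hull$points, 1, function(q)
        isTRUE(all.equal(unname(q), unname(proj[s, ])))))
    expect_false(strictly_outside, label = paste("mean outside hull for", key))
  }
  # zero-variance data: every resampled mean is identical
  da0 <- gen_da(cm, 0, 0, n_assessors = 5, replicates = 2, seed = 6)
  model0 <- pca_covariance(marginal_profiles(
    empirical_cell_means(da0, colnames(cm))))
  h0 <- bootstrap_hulls(da0, model0, B = 10, seed = 3)
  expect_true(all(vapply(h0, `[[`, logical(1), "degenerate")))
  expect_error(bootstrap_hulls(da, model, B = 1), "at least 2")
})

test_that("AHC merge order matches a hand-computed linkage on a 3-profile toy", {
  prof <- rbind(a = c(0, 0, 0, 0), b = c(1, 0, 0, 0), c = c(5, 5, 5, 0))
  # Euclidean distances: d(a,b)=1, d(a,c)=sqrt(75), d(b,c)=sqrt(66)
  hc <- ahc_profiles(prof, "dissimilarity")
  m <- hc$hclust$merge
  expect_identical(sort(m[1, ]), c(-2L, -1L)) # a,b merge first
  expect_equal(hc$hclust$height[1], 1, tolerance = 1e-12)
  # two identical profiles merge at height 0
  twin <- rbind(x = c(1, 2, 3), y = c(1, 2, 3), z = c(9, 1, 0))
  hcd <- ahc_profiles(twin, "dissimilarity")
  expect_equal(min(hcd$hclust$height), 0)
  # heights nondecreasing in both modes
  cm <- da_cell_means()$cells
  for (mode in c("dissimilarity", "similarity")) {
    h <- ahc_profiles(cm, mode)$hclust$height
    expect_true(all(diff(h) >= -1e-12))
  }
  # constant profile excluded with a warning in similarity mode
  flat <- rbind(cm[1:3, ], flatline = rep(4, ncol(cm)))
  expect_warning(ahc_profiles(flat, "similarity"), "constant profile")
})

test_that("the day-7 control sample is the most dissimilar at the 2-cluster cut", {
  cm <- da_cell_means()$cells
  for (mode in c("dissimilarity", "similarity")) {
    tree <- ahc_profiles(cm, mode)
    cl2 <- cutree(tree$hclust, 2)
    expect_equal(sum(cl2 == cl2[["CD7"]]), 1,
                 label = paste("CD7 singleton,", mode))
  }
})

test_that("attribute screening flags the calibrated effects", {
  cm <- da_cell_means()$cells[, c("umami", "color_intensity")]
  flat <- cbind(cm, no_effect = rep(6, 6))
  da <- gen_da(flat, 0.8, 1.0, 10, 3, seed = 12)
  sc <- da_screen(da)
  expect_true(sc$include[sc$attribute == "umami"])
  expect_lt(sc$p_treatment[sc$attribute == "umami"], 0.001)
  expect_true(sc$interaction_retained[sc$attribute == "color_intensity"])
  expect_false(sc$include[sc$attribute == "no_effect"])
})
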