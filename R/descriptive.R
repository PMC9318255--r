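#' Two-way ANOVA for one descriptive-analysis attribute
#'
#' Fits intensity ~ treatment * storage_day with sum-to-zero contrasts and
#' Type III sums of squares (equal to the classical two-way decomposition
#' under balance). Follows a sequential elimination rule for the interaction:
#' when the interaction p-value is at or above `drop_interaction_p` the
#' additive model is refitted and reported instead. Assessors and replicates
#' pool into the residual; the model's factors are treatment and day only.
#'
#' @param data long-format DA table: columns `assessor_id`, `treatment`,
#'   `storage_day`, `replicate`, `attribute`, `intensity`.
#' @param attribute name of the attribute to analyse.
#' @param drop_interaction_p elimination threshold for the interaction
#'   (default 0.1).
#' @return object of class `da_anova`: list with `attribute`, `table`
#'   (term, ss, df, statistic, p), `interaction_retained`, `model` (the
#'   retained `lm`), `data` (the analysed subset).
#' @export
da_anova <- function(data, attribute, drop_interaction_p = 0.1) {
  d <- data[data$attribute == attribute, , drop = FALSE]
  if (nrow(d) == 0L) stop("no records for attribute '", attribute, "'")
  d$treatment <- factor(d$treatment)
  d$storage_day <- factor(d$storage_day)
  if (nlevels(d$treatment) < 2L || nlevels(d$storage_day) < 2L)
    stop("need at least 2 levels of both treatment and storage day")
  if (any(table(d$treatment, d$storage_day) == 0L))
    stop("empty treatment x day cell(s) for attribute '", attribute, "'")
  if (length(unique(d$assessor_id)) < 2L)
    stop("single assessor: no residual basis for panel inference")
  ctr <- list(treatment = "contr.sum", storage_day = "contr.sum")
  full <- stats::lm(intensity ~ treatment * storage_day, data = d,
                    contrasts = ctr)
  a_full <- anova_table(full)
  p_int <- a_full["treatment:storage_day", "Pr(>F)"]
  retained <- is.finite(p_int) && p_int < drop_interaction_p
  model <- if (retained) full else
    stats::lm(intensity ~ treatment + storage_day, data = d, contrasts = ctr)
  a <- anova_table(model)
  keep <- setdiff(rownames(a), "(Intercept)")
  tab <- data.frame(term = keep,
                    ss = a[keep, "Sum Sq"],
                    df = a[keep, "Df"],
                    statistic = a[keep, "F value"],
                    p = a[keep, "Pr(>F)"],
                    row.names = NULL)
  tab$term <- sub("treatment:storage_day", "interaction", tab$term)
  tab$term <- sub("storage_day", "day", tab$term)
  tab$term <- sub("Residuals", "residual", tab$term)
  structure(
    list(attribute = attribute, table = tab,
         interaction_retained = retained,
         interaction_p = unname(p_int), model = model, data = d),
    class = "da_anova"
  )
}

# Type III table via car::Anova; a perfect (zero-residual) fit makes the
# F tests degenerate, so fall back to the sequential decomposition there
# (identical sums of squares under balance) with NA statistics.
anova_table <- function(model) {
  tryCatch(as.data.frame(car::Anova(model, type = 3)),
           error = function(e) {
    a <- as.data.frame(suppressWarnings(stats::anova(model)))
    names(a) <- c("Df", "Sum Sq", "Mean Sq", "F value", "Pr(>F)")
    a[, c("Sum Sq", "Df", "F value", "Pr(>F)")]
  })
}

#' Screen DA attributes by model significance
#'
#' Runs [da_anova()] for every attribute and flags those whose model shows
#' significance or a tendency (any factor p below `tendency`), the usual
#' filter for entering attributes into the sensory map.
#'
#' @inheritParams da_anova
#' @param tendency inclusion threshold on the model p-values (default 0.1).
#' @return data.frame with one row per attribute: p-values per term,
#'   `interaction_retained`, and `include`.
#' @export
da_screen <- function(data, tendency = 0.1, drop_interaction_p = 0.1) {
  attrs <- unique(data$attribute)
  rows <- lapply(attrs, function(a) {
    res <- da_anova(data, a, drop_interaction_p = drop_interaction_p)
    gp <- function(term) {
      i <- match(term, res$table$term)
      if (is.na(i)) NA_real_ else res$table$p[i]
    }
    data.frame(attribute = a,
               p_treatment = gp("treatment"), p_day = gp("day"),
               p_interaction = gp("interaction"),
               interaction_retained = res$interaction_retained)
  })
  out <- do.call(rbind, rows)
  ps <- out[, c("p_treatment", "p_day", "p_interaction")]
  out$include <- apply(ps, 1, function(p) any(p < tendency, na.rm = TRUE))
  out
}

#' Fisher's LSD post-hoc grouping with compact letter display
#'
#' All pairwise t tests between the level means of one design factor (or of
#' the treatment x day cells), using the residual mean square of the retained
#' ANOVA model. Levels are labelled by an insert-and-absorb compact letter
#' display: two levels share a letter iff their difference is not significant,
#' and 'a' is assigned to the highest mean.
#'
#' @param result a `da_anova` object.
#' @param factor `"treatment"`, `"storage_day"`, or `"cell"` (the
#'   treatment x day crossing).
#' @param alpha significance level (default 0.05).
#' @return object of class `lsd_grouping`: data.frame with `level`, `mean`,
#'   `n`, `letters`, plus attributes `pairwise` (matrix of p-values), `lsd`
#'   and `alpha`.
#' @export
fisher_lsd <- function(result, factor = c("treatment", "storage_day", "cell"),
                       alpha = 0.05) {
  if (!inherits(result, "da_anova")) stop("result must come from da_anova()")
  factor <- match.arg(factor)
  d <- result$data
  g <- switch(factor,
              treatment = d$treatment,
              storage_day = d$storage_day,
              cell = interaction(d$treatment, d$storage_day, sep = ":",
                                 drop = TRUE))
  res_df <- stats::df.residual(result$model)
  if (res_df < 1L) stop("zero residual degrees of freedom")
  mse <- sum(stats::residuals(result$model)^2) / res_df
  means <- tapply(d$intensity, g, mean)
  ns <- tapply(d$intensity, g, length)
  ord <- order(means, decreasing = TRUE)
  means <- means[ord]; ns <- ns[ord]
  k <- length(means)
  pmat <- matrix(1, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    tval <- if (se == 0) ifelse(means[i] == means[j], 0, Inf) else
      (means[i] - means[j]) / se
    pmat[i, j] <- pmat[j, i] <- 2 * stats::pt(-abs(tval), res_df)
  }
  letters_vec <- cld_insert_absorb(pmat < alpha)
  out <- data.frame(level = names(means), mean = as.numeric(means),
                    n = as.integer(ns), letters = letters_vec,
                    row.names = NULL)
  attr(out, "pairwise") <- pmat
  attr(out, "alpha") <- alpha
  attr(out, "lsd") <- stats::qt(1 - alpha / 2, res_df) *
    sqrt(mse * 2 / mean(ns))
  class(out) <- c("lsd_grouping", "data.frame")
  out
}

# Compact letter display by insert-and-absorb.
# `sig` is a logical k x k matrix (TRUE = the pair differs), rows ordered by
# descending mean; returns one letter string per row, 'a' on the highest mean.
cld_insert_absorb <- function(sig) {
  k <- nrow(sig)
  cols <- list(seq_len(k)) # each column = set of levels sharing a letter
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    hit <- vapply(cols, function(s) all(c(i, j) %in% s), logical(1))
    if (!any(hit)) next
    split_cols <- unlist(lapply(cols[hit], function(s)
      list(setdiff(s, i), setdiff(s, j))), recursive = FALSE)
    cols <- c(cols[!hit], split_cols)
    cols <- cols[lengths(cols) > 0]
    # absorb: drop any column contained in another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] && all(cols[[a]] %in% cols[[b]]) &&
          length(cols[[a]]) < length(cols[[b]]))
        keep[a] <- FALSE
    }
    cols <- unique(cols[keep])
  }
  # order columns by their best (lowest-index = highest-mean) member
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  out <- character(k)
  for (ci in seq_along(cols))
    for (lv in cols[[ci]])
      out[lv] <- paste0(out[lv], letters[ci])
  out
}

#' Covariance PCA with supplementary observations and Varimax rotation
#'
#' Column-centered principal component analysis on the covariance matrix of
#' the active observations. Supplementary rows are centered with the active
#' column means and projected onto the active loadings without influencing
#' them. Optionally the first `k` components are Varimax-rotated
#' (Kaiser-normalized); explained variance is reported both before and after
#' rotation, as fractions of the total variance.
#'
#' @param x numeric matrix, active observations x attributes (rownames kept).
#' @param supplementary optional matrix of supplementary observations with
#'   the same columns.
#' @param rotate logical; Varimax-rotate the first `k` components.
#' @param k number of components to rotate (default 2).
#' @return object of class `pca_covariance`: list with `scores`, `loadings`
#'   (attribute loadings scaled by component sd), `axes` (orthonormal
#'   directions), `explained` (variance fractions, all components), `center`,
#'   `supplementary_scores`, and when rotated: `rotated` with `loadings`,
#'   `axes`, `scores`, `supplementary_scores`, `explained` (fractions for the
#'   k rotated factors).
#' @export
pca_covariance <- function(x, supplementary = NULL, rotate = FALSE, k = 2) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 active observations")
  if (all(apply(x, 2, stats::sd) == 0)) stop("constant matrix: no variance")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  nz <- sum(ev > max(ev) * 1e-12)
  explained <- ev / sum(ev)
  proj <- function(m) {
    sweep(as.matrix(m), 2, p$center) %*% p$rotation
  }
  sup_scores <- if (is.null(supplementary)) NULL else proj(supplementary)
  out <- list(scores = p$x,
              axes = p$rotation,
              loadings = p$rotation %*% diag(p$sdev, length(p$sdev)),
              sdev = p$sdev,
              explained = explained,
              center = p$center,
              supplementary_scores = sup_scores,
              k = k, rotated = NULL)
  if (rotate) {
    k <- min(k, nz)
    L <- p$rotation[, 1:k, drop = FALSE] %*% diag(p$sdev[1:k], k)
    vm <- stats::varimax(L, normalize = TRUE, eps = 1e-10)
    R <- vm$rotmat
    axes_r <- p$rotation[, 1:k, drop = FALSE] %*% R
    Lr <- L %*% R
    rot_var <- colSums(Lr^2)
    ord <- order(rot_var, decreasing = TRUE)
    axes_r <- axes_r[, ord, drop = FALSE]
    Lr <- Lr[, ord, drop = FALSE]
    rot_var <- rot_var[ord]
    colnames(axes_r) <- colnames(Lr) <- paste0("F", 1:k)
    ctr <- function(m) sweep(as.matrix(m), 2, p$center)
    out$rotated <- list(
      loadings = Lr, axes = axes_r,
      scores = ctr(x) %*% axes_r,
      supplementary_scores = if (is.null(supplementary)) NULL else
        ctr(supplementary) %*% axes_r,
      explained = rot_var / sum(ev))
  }
  class(out) <- "pca_covariance"
  out
}

#' Partial-bootstrap convex hulls of sample positions in a sensory map
#'
#' Resamples assessors with replacement `B` times; in each resample the
#' treatment x day sample mean profiles are projected as supplementary
#' observations onto the (fixed) PCA axes, and the per-sample convex hull of
#' the projected clouds summarises sample-position uncertainty by its most
#' extreme observations.
#'
#' @param data long-format DA table (see [da_anova()]).
#' @param model a `pca_covariance` fit whose variables are DA attributes.
#' @param B number of bootstrap resamples (default 200, >= 2).
#' @param seed integer seed; the vertex set is reproducible given the seed.
#' @return named list, one element per sample: list with `points` (B x 2
#'   matrix of projected means on the first two axes), `hull` (vertex
#'   coordinates, ordered), and `degenerate` (TRUE when the cloud collapses
#'   to a point).
#' @export
bootstrap_hulls <- function(data, model, B = 200, seed = 1) {
  if (B < 2) stop("need at least 2 bootstrap resamples")
  vars <- rownames(model$axes)
  axes <- if (!is.null(model$rotated)) model$rotated$axes[, 1:2] else
    model$axes[, 1:2]
  assessors <- unique(data$assessor_id)
  data$sample <- interaction(data$treatment, data$storage_day, sep = ":",
                             drop = TRUE)
  samples <- levels(data$sample)
  per_sample <- table(data$sample, data$assessor_id)
  pts <- array(NA_real_, c(B, 2, length(samples)),
               dimnames = list(NULL, c("F1", "F2"), samples))
  local_seed(seed)
  for (b in seq_len(B)) {
    take <- sample(assessors, length(assessors), replace = TRUE)
    boot <- do.call(rbind, lapply(take, function(a)
      data[data$assessor_id == a, , drop = FALSE]))
    for (s in samples) {
      sub <- boot[boot$sample == s, , drop = FALSE]
      prof <- tapply(sub$intensity, sub$attribute, mean)[vars]
      pts[b, , s] <- (prof - model$center[vars]) %*% axes[vars, ]
    }
  }
  out <- lapply(samples, function(s) {
    m <- pts[, , s]
    degenerate <- nrow(unique(round(m, 12))) == 1L
    hull_idx <- if (degenerate) 1L else grDevices::chull(m)
    list(points = m, hull = m[hull_idx, , drop = FALSE],
         degenerate = degenerate)
  })
  names(out) <- samples
  out
}

#' Agglomerative hierarchical clustering of sample profiles
#'
#' Similarity mode clusters on 1 - Pearson correlation between profiles with
#' complete linkage; dissimilarity mode on Euclidean distance with Ward's
#' criterion (heights on the original distance scale). The truncation cut is
#' chosen, among all cluster counts from 2 to n-1, as the partition whose
#' cluster-size distribution has maximum Shannon entropy; ties go to the
#' fewest clusters.
#'
#' @param profiles numeric matrix, samples x attributes, with rownames.
#' @param mode `"dissimilarity"` (Euclidean + Ward) or `"similarity"`
#'   (1 - Pearson r + complete linkage).
#' @return object of class `ahc_tree`: list with `hclust`, `mode`, `k`
#'   (entropy cut), `clusters` (named membership at the cut), `entropy`
#'   (per candidate k), `excluded` (constant profiles dropped in similarity
#'   mode).
#' @export
ahc_profiles <- function(profiles, mode = c("dissimilarity", "similarity")) {
  mode <- match.arg(mode)
  profiles <- as.matrix(profiles)
  excluded <- character(0)
  if (mode == "similarity") {
    const <- apply(profiles, 1, stats::sd) == 0
    if (any(const)) {
      excluded <- rownames(profiles)[const]
      warning("constant profile(s) excluded (undefined correlation): ",
              paste(excluded, collapse = ", "))
      profiles <- profiles[!const, , drop = FALSE]
    }
  }
  if (nrow(profiles) < 2L) stop("need at least 2 profiles to cluster")
  if (mode == "similarity") {
    d <- stats::as.dist(1 - stats::cor(t(profiles)))
    hc <- stats::hclust(d, method = "complete")
  } else {
    d <- stats::dist(profiles)
    hc <- stats::hclust(d, method = "ward.D2")
  }
  n <- nrow(profiles)
  ks <- if (n > 2L) 2:(n - 1L) else 2L
  ent <- vapply(ks, function(k) {
    sizes <- table(stats::cutree(hc, k))
    p <- sizes / sum(sizes)
    -sum(p * log(p))
  }, numeric(1))
  k_best <- ks[which.max(ent)] # which.max takes the first max: fewest clusters
  structure(
    list(hclust = hc, mode = mode, k = k_best,
         clusters = stats::cutree(hc, k_best),
         entropy = stats::setNames(ent, ks),
         excluded = excluded),
    class = "ahc_tree"
  )
}

#' Packaged cooked-fillet sensory mean intensities
#'
#' The 31 attribute x 6 sample table of mean intensities for cooked gilthead
#' seabream fillets: Control and treated (osmotically dehydrated) fillets at
#' storage days 1, 5 and 7 (samples CD1, CD5, CD7, SD1, SD5, SD7), for every
#' attribute whose two-way model showed significance or a tendency (p < 0.1).
#'
#' @return list with `cells` (6 x 31 matrix, samples x attributes) and
#'   `meta` (data.frame of attribute and modality).
#' @export
da_cell_means <- function() {
  path <- system.file("extdata", "da_cell_means.csv",
                      package = "shelfsense", mustWork = TRUE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  cells <- t(as.matrix(m[, c("CD1", "CD5", "CD7", "SD1", "SD5", "SD7")]))
  colnames(cells) <- m$attribute
  list(cells = cells, meta = m[, c("attribute", "modality")])
}

#' Factor-level marginal mean profiles from a sample x attribute table
#'
#' Averages the treatment x day cell profiles into the five design-factor
#' level profiles (Control, SUSEA, D1, D5, D7) that serve as active
#' observations in the factor-level sensory map.
#'
#' @param cells 6 x p matrix with rownames CD1, CD5, CD7, SD1, SD5, SD7.
#' @return 5 x p matrix with rownames Control, SUSEA, D1, D5, D7.
#' @export
marginal_profiles <- function(cells) {
  need <- c("CD1", "CD5", "CD7", "SD1", "SD5", "SD7")
  if (!all(need %in% rownames(cells)))
    stop("cells must have rownames ", paste(need, collapse = ", "))
  rbind(
    Control = colMeans(cells[c("CD1", "CD5", "CD7"), , drop = FALSE]),
    SUSEA   = colMeans(cells[c("SD1", "SD5", "SD7"), , drop = FALSE]),
    D1      = colMeans(cells[c("CD1", "SD1"), , drop = FALSE]),
    D5      = colMeans(cells[c("CD5", "SD5"), , drop = FALSE]),
    D7      = colMeans(cells[c("CD7", "SD7"), , drop = FALSE])
  )
}
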