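# CSV schemas shared by the readers and the generators. Validation collects
# row-level problems with line numbers rather than failing on the first.

schema_defs <- list(
  qim_scores = list(
    required = c("storage_day", "assessor_id", "fillet_id", "treatment",
                 "color", "discoloration", "brightness", "odor", "firmness",
                 "elasticity", "acceptable"),
    check = function(d) {
      probs <- character(0)
      demerits <- c(color = 2, discoloration = 2, brightness = 2, odor = 3,
                    firmness = 2, elasticity = 2)
      for (a in names(demerits)) {
        bad <- which(!is.finite(d[[a]]) | d[[a]] < 0 | d[[a]] > demerits[[a]] |
                       d[[a]] != round(d[[a]]))
        if (length(bad))
          probs <- c(probs, paste0("row ", bad, ": ", a,
                                   " outside demerit range 0-", demerits[[a]]))
      }
      bad <- which(!d$acceptable %in% c(0, 1))
      if (length(bad))
        probs <- c(probs, paste0("row ", bad, ": acceptable must be 0/1"))
      bad <- which(!is.finite(d$storage_day) | d$storage_day < 0)
      if (length(bad))
        probs <- c(probs, paste0("row ", bad, ": negative storage_day"))
      probs
    }),
  growth_counts = list(
    required = c("storage_day", "treatment", "organism", "replicate",
                 "log10_cfu_g"),
    check = function(d) {
      probs <- character(0)
      bad <- which(!is.finite(d$log10_cfu_g))
      if (length(bad))
        probs <- c(probs, paste0("row ", bad, ": unparseable log10_cfu_g"))
      bad <- which(!is.finite(d$storage_day) | d$storage_day < 0)
      if (length(bad))
        probs <- c(probs, paste0("row ", bad, ": negative storage_day"))
      probs
    }),
  da_scores = list(
    required = c("assessor_id", "treatment", "storage_day", "replicate",
                 "attribute", "intensity"),
    check = function(d) {
      bad <- which(!is.finite(d$intensity) | d$intensity < 0 |
                     d$intensity > 150)
      if (length(bad))
        paste0("row ", bad, ": intensity outside the 0-150 scale")
      else character(0)
    })
)

#' Read and validate a study CSV table
#'
#' @param path CSV file (UTF-8, comma separator, `.` decimal, header row).
#' @param schema one of `"qim_scores"`, `"growth_counts"`, `"da_scores"`.
#' @return validated data.frame.
#' @export
load_table <- function(path, schema = names(schema_defs)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  def <- schema_defs[[schema]]
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(def$required, names(d))
  if (length(missing))
    stop("table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  probs <- def$check(d)
  if (length(probs))
    stop("validation of '", path, "' failed:\n  ",
         paste(utils::head(probs, 10), collapse = "\n  "))
  d
}

#' @rdname load_table
#' @param data data.frame matching the schema (validated before writing).
#' @export
write_table <- function(data, path, schema = names(schema_defs)) {
  schema <- match.arg(schema)
  def <- schema_defs[[schema]]
  missing <- setdiff(def$required, names(data))
  if (length(missing))
    stop("data lacks column(s): ", paste(missing, collapse = ", "))
  probs <- def$check(data)
  if (length(probs))
    stop("refusing to write invalid table:\n  ",
         paste(utils::head(probs, 10), collapse = "\n  "))
  utils::write.csv(data[, def$required, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full shelf-life inference pipeline
#'
#' Orchestrates every stage on one set of inputs: QIM aggregation, trend
#' fitting and shelf-life estimation per treatment; tetrad difference and
#' similarity analysis with d' estimation and panel-size planning; Baranyi
#' fits per organism x treatment with QI-count correlations; and the DA stack
#' (attribute screening, per-attribute ANOVA + LSD, factor-level covariance
#' PCA with Varimax and the samples as supplementary observations, AHC in
#' both modes). Inputs default to the synthetic study conditions; pass
#' data.frames (e.g. from [load_table()]) to analyse real data.
#'
#' @param seed integer seed used for every generated input.
#' @param config a [synthetic_config()].
#' @param qim,growth,da optional data.frames overriding the generated inputs.
#' @param tetrad optional list with `n_assessors` and `n_correct`.
#' @return nested report list (class `shelfsense_report`), serialisable with
#'   [write_report()].
#' @export
run_pipeline <- function(seed = 1, config = synthetic_config(),
                         qim = NULL, tetrad = NULL, growth = NULL, da = NULL) {
  scheme <- seabream_fillet_scheme()
  if (is.null(qim)) qim <- gen_qim(config, seed = seed, scheme = scheme)
  if (is.null(tetrad))
    tetrad <- gen_tetrad(config$tetrad$n, config$tetrad$dprime, seed = seed)
  if (is.null(growth))
    growth <- gen_growth(config$growth$params, config$growth$days,
                         config$growth$sd, config$growth$replicates,
                         seed = seed)
  if (is.null(da))
    da <- gen_da(sd_assessor = config$da$sd_assessor,
                 sd_replicate = config$da$sd_replicate,
                 n_assessors = config$da$n_assessors,
                 replicates = config$da$replicates, seed = seed)

  ## --- QIM stage -----------------------------------------------------------
  rej <- rejection_threshold(qim, scheme)
  qim_stage <- list(rejection_qi = rej)
  series <- list()
  for (trt in unique(qim$treatment)) {
    s <- aggregate_qi(qim[qim$treatment == trt, ], scheme)
    fit <- fit_qi_trend(s)
    sl <- shelf_life_days(fit, rej)
    series[[trt]] <- s
    qim_stage[[trt]] <- list(
      slope = fit$slope, intercept = fit$intercept, r_squared = fit$r_squared,
      crossing_time = sl$crossing_time, shelf_life_days = sl$shelf_life_days)
  }
  if (all(c("Control", "Treated") %in% names(qim_stage)))
    qim_stage$extension_percent <- extension_percent(
      qim_stage$Control$shelf_life_days, qim_stage$Treated$shelf_life_days)

  ## --- tetrad stage --------------------------------------------------------
  n <- tetrad$n_assessors; x <- tetrad$n_correct
  plan <- tetrad_sample_size(config$tetrad$dprime, alpha = 0.1,
                             target_power = 0.9)
  tetrad_stage <- list(
    n_assessors = n, n_correct = x,
    difference = tetrad_difference_test(n, x),
    similarity = tetrad_similarity_test(n, x, config$tetrad$dprime),
    dprime = estimate_dprime(n, x),
    plan = plan[c("n", "critical_value", "power", "pc0")])

  ## --- growth stage --------------------------------------------------------
  growth_stage <- list()
  for (org in unique(growth$organism)) for (trt in unique(growth$treatment)) {
    g <- growth[growth$organism == org & growth$treatment == trt, ]
    if (nrow(g) == 0L) next
    fit <- fit_baranyi(g$storage_day, g$log10_cfu_g, with_lag = "auto")
    key <- paste(org, trt, sep = ".")
    growth_stage[[key]] <- list(
      y0 = fit$params$y0, mu_max = fit$params$mu_max,
      lag = fit$params$lag, ymax = fit$params$ymax,
      r_squared = fit$r_squared, with_lag = fit$with_lag)
    if (trt %in% names(series)) {
      qtr <- if (trt == "Treated" && !"Treated" %in% unique(qim$treatment))
        NULL else series[[trt]]
      if (!is.null(qtr)) {
        cm <- aggregate_counts(g)
        corr <- tryCatch(qi_count_correlation(qtr, cm), error = function(e) NULL)
        if (!is.null(corr))
          growth_stage[[key]]$qi_correlation <- corr[c("r", "p_r", "n")]
      }
    }
  }

  ## --- descriptive stage ---------------------------------------------------
  screen <- da_screen(da)
  included <- screen$attribute[screen$include]
  anovas <- lapply(stats::setNames(nm = included), function(a) {
    res <- da_anova(da, a)
    lsd_factor <- if (res$interaction_retained) "cell" else
      res$table$term[which.min(res$table$p[res$table$term != "residual"])]
    if (!lsd_factor %in% c("treatment", "cell")) lsd_factor <- "storage_day"
    list(table = res$table, interaction_retained = res$interaction_retained,
         lsd = as.data.frame(fisher_lsd(res, lsd_factor)))
  })
  cell_means <- empirical_cell_means(da, included)
  marg <- marginal_profiles(cell_means)
  pca <- pca_covariance(marg, supplementary = cell_means, rotate = TRUE, k = 2)
  ahc_d <- ahc_profiles(cell_means, "dissimilarity")
  ahc_s <- ahc_profiles(cell_means, "similarity")
  da_stage <- list(
    screen = screen,
    anova = anovas,
    pca = list(explained = pca$explained,
               f12_percent = 100 * sum(pca$explained[1:2]),
               rotated_explained = pca$rotated$explained),
    ahc = list(dissimilarity = list(k = ahc_d$k, clusters = ahc_d$clusters),
               similarity = list(k = ahc_s$k, clusters = ahc_s$clusters)))

  structure(
    list(seed = seed, qim = qim_stage, tetrad = tetrad_stage,
         growth = growth_stage, descriptive = da_stage),
    class = "shelfsense_report")
}

#' Empirical treatment x day cell mean profiles of a DA dataset
#'
#' @param da long DA data.frame.
#' @param attributes attributes to include (default: all present).
#' @return samples x attributes matrix with CD1-style rownames.
#' @export
empirical_cell_means <- function(da, attributes = unique(da$attribute)) {
  d <- da[da$attribute %in% attributes, ]
  key <- paste0(ifelse(d$treatment == "Control", "C", "S"), "D", d$storage_day)
  m <- tapply(d$intensity, list(key, d$attribute), mean)
  m[, attributes, drop = FALSE]
}

#' Serialise a pipeline report to JSON
#'
#' @param report a `shelfsense_report` (or any list).
#' @param path output file.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
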