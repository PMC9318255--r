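# Seed hygiene: run a block under a fixed seed, restoring the caller's RNG
# state on exit so generators are pure functions of (config, seed).
local_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  expr <- if (is.null(old))
    quote(rm(".Random.seed", envir = globalenv()))
  else
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(NULL)
}

#' Default study configuration for the synthetic generators
#'
#' Encodes the study conditions the generators emulate: QI deterioration
#' lines (Control slope 0.7318, intercept 0.8183; treated slope 0.5655,
#' intercept 0.8839 demerit points/day), assessor noise 0.8 points, rejection
#' threshold 6; a 36-assessor tetrad at d' = 1.2; Baranyi kinetics for total
#' viable counts (TVC) and Pseudomonas under both treatments (rates
#' 0.559/0.464 and 0.908/0.742 log10/day, lags 0/0 and 2.3/2.7 d, asymptote
#' 9.8 log10 CFU/g) with plate noise 0.2 log10 and 2 replicates; and the
#' packaged cooked-fillet cell-mean table with assessor sd 0.8 and replicate
#' sd 1.0 intensity units over 10 assessors x 3 replicates.
#'
#' @param ... named overrides of top-level entries (`qim`, `tetrad`,
#'   `growth`, `da`), each replacing the default sublist wholesale.
#' @return nested list of class `synthetic_config`.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    qim = list(
      lines = data.frame(
        treatment = c("Control", "Treated"),
        slope = c(0.7318, 0.5655),
        intercept = c(0.8183, 0.8839)),
      days = list(Control = c(1, 5, 7, 8, 11),
                  Treated = c(1, 5, 7, 8, 11, 13)),
      sd = 0.8, threshold = 6, judges = 5:8, fillets = 3),
    tetrad = list(n = 36, dprime = 1.2),
    growth = list(
      params = data.frame(
        organism = c("TVC", "TVC", "Pseudomonas", "Pseudomonas"),
        treatment = c("Control", "Treated", "Control", "Treated"),
        y0 = c(5.6, 5.1, 5.4, 4.9),
        mu_max = c(0.559, 0.464, 0.908, 0.742),
        lag = c(0, 0, 2.3, 2.7),
        ymax = c(9.8, 9.8, 9.8, 9.8)),
      days = 0:13, sd = 0.2, replicates = 2),
    da = list(sd_assessor = 0.8, sd_replicate = 1.0,
              n_assessors = 10, replicates = 3)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "synthetic_config")
}

#' Simulate a QIM panel
#'
#' Latent QI per evaluation is `intercept + slope * day + N(0, sd)`. Within
#' each session (treatment x day) the latent values are converted to integer
#' QI by largest-remainder rounding: each record gets the floor of its latent
#' QI and the records with the largest fractional parts are bumped by one
#' until the session total matches the rounded latent total. The session mean
#' therefore tracks the latent mean to within half a point divided by the
#' panel size, and with zero noise the day means sit on the generating line
#' up to that granularity. The integer QI is then allocated greedily to
#' attribute demerits in scheme order (each attribute filled to its maximum
#' before the next). A fillet is flagged unacceptable when its realised
#' integer QI reaches the rejection threshold, so the minimum unacceptable QI
#' equals the threshold whenever the generated panel reaches it.
#'
#' @param config a [synthetic_config()] (its `qim` entry is used).
#' @param seed integer seed.
#' @param scheme a [qim_scheme()]; defaults to the packaged seabream scheme.
#' @return long evaluation data.frame in the layout [aggregate_qi()] expects,
#'   with an `acceptable` flag.
#' @export
gen_qim <- function(config = synthetic_config(), seed = 1,
                    scheme = seabream_fillet_scheme()) {
  q <- config$qim
  if (any(q$lines$slope < 0)) stop("QI slopes must be nonnegative")
  local_seed(seed)
  rows <- list()
  for (i in seq_len(nrow(q$lines))) {
    trt <- q$lines$treatment[i]
    for (day in q$days[[trt]]) {
      n_j <- if (length(q$judges) > 1L) sample(q$judges, 1) else q$judges
      grid <- expand.grid(judge = seq_len(n_j), fillet = seq_len(q$fillets))
      latent <- q$lines$intercept[i] + q$lines$slope[i] * day +
        stats::rnorm(nrow(grid), 0, q$sd)
      qi <- session_qi(latent, scheme$max_qi)
      scores <- t(vapply(qi, allocate_demerits, scheme$max_demerit,
                         scheme = scheme))
      rows[[length(rows) + 1L]] <- data.frame(
        storage_day = day,
        assessor_id = sprintf("J%02d", grid$judge),
        fillet_id = sprintf("%s-D%d-F%d", substr(trt, 1, 1), day,
                            grid$fillet),
        treatment = trt,
        scores,
        acceptable = as.integer(qi < q$threshold))
    }
  }
  do.call(rbind, rows)
}

# Largest-remainder integer rounding of a session's latent QI values: floors
# plus one extra point to the records with the largest fractional parts, so
# the session total matches the rounded latent total.
session_qi <- function(latent, max_qi) {
  l <- pmin(pmax(latent, 0), max_qi)
  base <- floor(l)
  frac <- l - base
  k <- round(sum(frac))
  qi <- as.integer(base)
  if (k > 0) {
    bump <- order(frac, decreasing = TRUE)[seq_len(k)]
    qi[bump] <- qi[bump] + 1L
  }
  pmin(qi, as.integer(max_qi))
}

# Distribute a total QI over attributes greedily, in scheme order, capping at
# each attribute's maximum. Only the total matters downstream.
allocate_demerits <- function(qi, scheme) {
  maxima <- scheme$max_demerit
  out <- stats::setNames(integer(length(maxima)), names(maxima))
  left <- qi
  for (a in names(maxima)) {
    take <- min(left, maxima[[a]])
    out[[a]] <- take
    left <- left - take
  }
  if (left > 0) stop("QI ", qi, " exceeds the scheme maximum")
  out
}

#' Simulate a tetrad experiment
#'
#' `latent` mode draws each assessor's four percepts (two N(0,1), two
#' N(dprime,1)) and applies the sorted-adjacency grouping rule: the response
#' is correct when both samples of one product flank the other's. `bernoulli`
#' mode draws correct responses directly at probability
#' [tetrad_pc()]`(dprime)`.
#'
#' @param n number of assessors.
#' @param dprime sensory distance (>= 0).
#' @param seed integer seed.
#' @param mode `"latent"` or `"bernoulli"`.
#' @return list with `n_assessors`, `n_correct`, and `responses`
#'   (data.frame of assessor_id, correct).
#' @export
gen_tetrad <- function(n, dprime, seed = 1, mode = c("latent", "bernoulli")) {
  mode <- match.arg(mode)
  if (n < 1) stop("n must be at least 1")
  if (dprime < 0) stop("dprime must be nonnegative")
  local_seed(seed)
  correct <- if (mode == "latent") {
    a1 <- stats::rnorm(n); a2 <- stats::rnorm(n)
    b1 <- stats::rnorm(n, dprime); b2 <- stats::rnorm(n, dprime)
    pmax(a1, a2) < pmin(b1, b2) | pmax(b1, b2) < pmin(a1, a2)
  } else {
    stats::runif(n) < tetrad_pc(dprime)
  }
  list(n_assessors = n, n_correct = sum(correct),
       responses = data.frame(assessor_id = sprintf("A%03d", seq_len(n)),
                              correct = as.integer(correct)))
}

#' Simulate plate-count growth curves
#'
#' Log10 counts are the Baranyi-Roberts mean curve plus independent
#' Gaussian plate noise, per replicate.
#'
#' @param params data.frame with columns `organism`, `treatment`, `y0`,
#'   `mu_max`, `lag`, `ymax` (one curve per row).
#' @param days sampling days.
#' @param sd plate noise, log10 units.
#' @param replicates plate replicates per time point.
#' @param seed integer seed.
#' @return long data.frame: `storage_day`, `treatment`, `organism`,
#'   `replicate`, `log10_cfu_g`.
#' @export
gen_growth <- function(params, days = 0:13, sd = 0.2, replicates = 2,
                       seed = 1) {
  if (sd < 0) stop("sd must be nonnegative")
  local_seed(seed)
  rows <- list()
  for (i in seq_len(nrow(params))) {
    mu <- baranyi_log10(days, params$y0[i], params$mu_max[i],
                        params$ymax[i], params$lag[i])
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        storage_day = days,
        treatment = params$treatment[i],
        organism = params$organism[i],
        replicate = sprintf("R%d", r),
        log10_cfu_g = mu + stats::rnorm(length(days), 0, sd))
    }
  }
  do.call(rbind, rows)
}

#' Simulate a descriptive-analysis dataset
#'
#' Intensity = cell mean + assessor offset (one N(0, sd_assessor) draw per
#' assessor x attribute, constant over samples and replicates) + replicate
#' residual N(0, sd_replicate), clipped to the 0-150 line scale. The design
#' is balanced: every assessor scores every sample in every replicate.
#'
#' @param cell_means samples x attributes matrix with rownames of the form
#'   CD1/SD5 (treatment letter + storage day); defaults to the packaged
#'   cooked-fillet table.
#' @param sd_assessor assessor offset sd (intensity units).
#' @param sd_replicate residual sd (intensity units).
#' @param n_assessors panel size.
#' @param replicates replications per sample.
#' @param seed integer seed.
#' @return long DA data.frame: `assessor_id`, `treatment`, `storage_day`,
#'   `replicate`, `attribute`, `intensity`.
#' @export
gen_da <- function(cell_means = da_cell_means()$cells, sd_assessor = 0.8,
                   sd_replicate = 1.0, n_assessors = 10, replicates = 3,
                   seed = 1) {
  if (any(cell_means < 0 | cell_means > 150))
    stop("cell means must lie on the 0-150 scale")
  if (sd_assessor < 0 || sd_replicate < 0) stop("sds must be nonnegative")
  local_seed(seed)
  attrs <- colnames(cell_means)
  samples <- rownames(cell_means)
  trt <- ifelse(substr(samples, 1, 1) == "C", "Control", "SUSEA")
  day <- as.integer(sub("^[CS]D", "", samples))
  offsets <- matrix(stats::rnorm(n_assessors * length(attrs), 0, sd_assessor),
                    n_assessors, length(attrs),
                    dimnames = list(NULL, attrs))
  grid <- expand.grid(assessor = seq_len(n_assessors),
                      replicate = seq_len(replicates),
                      sample = seq_along(samples),
                      attribute = seq_along(attrs))
  mu <- cell_means[cbind(grid$sample, grid$attribute)] +
    offsets[cbind(grid$assessor, grid$attribute)]
  intensity <- mu + stats::rnorm(nrow(grid), 0, sd_replicate)
  data.frame(
    assessor_id = sprintf("P%02d", grid$assessor),
    treatment = trt[grid$sample],
    storage_day = day[grid$sample],
    replicate = grid$replicate,
    attribute = attrs[grid$attribute],
    intensity = pmin(150, pmax(0, intensity)))
}
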