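#' Construct a QIM demerit scheme
#'
#' The Quality Index Method (QIM) scores each of a set of appearance, odor and
#' texture attributes on a small integer demerit scale (0 = very fresh) and
#' sums them into the Quality Index (QI). A scheme fixes the attribute list,
#' the per-attribute demerit maxima, and the level descriptions shown to
#' judges.
#'
#' @param attributes data.frame with columns `modality`, `attribute`,
#'   `demerit` (integer level) and `description`, one row per level. Levels of
#'   each attribute must be consecutive integers starting at 0.
#' @return An object of class `qim_scheme`: list with `attributes` (the level
#'   table), `max_demerit` (named integer vector) and `max_qi` (the scheme
#'   maximum QI, i.e. the sum of per-attribute maxima).
#' @seealso [seabream_fillet_scheme()] for the packaged default,
#'   [validate_scheme()], [total_qi()]
#' @export
qim_scheme <- function(attributes) {
  required <- c("modality", "attribute", "demerit", "description")
  if (!is.data.frame(attributes) || !all(required %in% names(attributes)))
    stop("`attributes` must be a data.frame with columns ",
         paste(required, collapse = ", "))
  if (nrow(attributes) == 0L) stop("empty scheme: no attribute levels")
  attributes$demerit <- as.integer(attributes$demerit)
  attr_names <- unique(attributes$attribute)
  max_demerit <- integer(length(attr_names))
  names(max_demerit) <- attr_names
  for (a in attr_names) {
    lv <- sort(attributes$demerit[attributes$attribute == a])
    if (anyDuplicated(lv))
      stop("duplicate demerit level for attribute '", a, "'")
    if (!identical(lv, seq.int(0L, length(lv) - 1L)))
      stop("demerit levels of attribute '", a,
           "' must be consecutive integers starting at 0")
    if (length(lv) < 2L)
      stop("attribute '", a, "' has a single level; no demerit range")
    max_demerit[a] <- max(lv)
  }
  structure(
    list(attributes = attributes, max_demerit = max_demerit,
         max_qi = sum(max_demerit)),
    class = "qim_scheme"
  )
}

#' Packaged QIM scheme for gilthead seabream fillets
#'
#' Six attributes: appearance (color, discoloration, brightness; 0-2 each),
#' odor quality (0-3) and texture (firmness, elasticity; 0-2 each), giving a
#' QI range of 0-13 demerit points.
#'
#' @return A [qim_scheme()] object with `max_qi = 13`.
#' @export
seabream_fillet_scheme <- function() {
  path <- system.file("extdata", "qim_scheme_seabream.csv",
                      package = "shelfsense", mustWork = TRUE)
  qim_scheme(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Validate a QIM scheme and summarise its score space
#'
#' @param scheme a [qim_scheme()] object (re-validated on entry).
#' @return list with `n_attributes`, `max_qi` and `ranges` (named integer
#'   vector of per-attribute maxima).
#' @export
validate_scheme <- function(scheme) {
  if (!inherits(scheme, "qim_scheme")) stop("not a qim_scheme object")
  scheme <- qim_scheme(scheme$attributes)  # re-run structural checks
  list(n_attributes = length(scheme$max_demerit),
       max_qi = scheme$max_qi,
       ranges = scheme$max_demerit)
}

#' Total Quality Index of one evaluation
#'
#' Sums the per-attribute demerit points of a single fillet evaluation.
#'
#' @param scores named integer vector (or 1-row data.frame) of demerit points,
#'   one entry per scheme attribute.
#' @param scheme a [qim_scheme()] object.
#' @return integer QI in `[0, scheme$max_qi]`.
#' @export
total_qi <- function(scores, scheme) {
  if (!inherits(scheme, "qim_scheme")) stop("not a qim_scheme object")
  if (is.data.frame(scores)) scores <- unlist(scores[1, , drop = TRUE])
  need <- names(scheme$max_demerit)
  missing <- setdiff(need, names(scores))
  if (length(missing))
    stop("missing attribute score(s): ", paste(missing, collapse = ", "))
  s <- scores[need]
  if (anyNA(s) || any(s != round(s))) stop("demerit scores must be integers")
  s <- as.integer(round(s))
  out_of_range <- s < 0L | s > scheme$max_demerit
  if (any(out_of_range))
    stop("score out of demerit range for: ",
         paste(need[out_of_range], collapse = ", "))
  sum(s)
}

#' Aggregate panel evaluations into a QI time series
#'
#' Computes, per storage day, the mean total QI over all assessor x fillet
#' records present that day (unbalanced panels are allowed; the mean is a
#' simple mean over available records, with no assessor weighting).
#'
#' @param evaluations data.frame in the long evaluation layout: columns
#'   `storage_day`, `assessor_id`, `fillet_id`, plus one integer column per
#'   scheme attribute (an `acceptable` column and any other metadata are
#'   carried through untouched).
#' @param scheme a [qim_scheme()] object.
#' @return data.frame of class `qi_series` with columns `storage_day`,
#'   `mean_qi`, `sd_qi`, `n`, ordered by day.
#' @export
aggregate_qi <- function(evaluations, scheme) {
  if (!is.data.frame(evaluations) || nrow(evaluations) == 0L)
    stop("no evaluations to aggregate")
  qi <- evaluation_qi(evaluations, scheme)
  day <- evaluations$storage_day
  if (is.null(day)) stop("evaluations lack a storage_day column")
  agg <- do.call(rbind, lapply(split(qi, day), function(v)
    data.frame(mean_qi = mean(v), sd_qi = stats::sd(v), n = length(v))))
  out <- data.frame(storage_day = as.numeric(rownames(agg)), agg,
                    row.names = NULL)
  out <- out[order(out$storage_day), , drop = FALSE]
  class(out) <- c("qi_series", "data.frame")
  out
}

#' Per-record total QI for a long evaluation table
#'
#' @inheritParams aggregate_qi
#' @return integer vector of total QI, one per row.
#' @export
evaluation_qi <- function(evaluations, scheme) {
  need <- names(scheme$max_demerit)
  missing <- setdiff(need, names(evaluations))
  if (length(missing))
    stop("evaluation table lacks attribute column(s): ",
         paste(missing, collapse = ", "))
  m <- as.matrix(evaluations[, need, drop = FALSE])
  if (anyNA(m) || any(m != round(m))) stop("demerit scores must be integers")
  bad <- sweep(m, 2, scheme$max_demerit, ">") | m < 0
  if (any(bad)) {
    rows <- which(apply(bad, 1, any))
    stop("demerit score out of range in row(s): ",
         paste(utils::head(rows, 5), collapse = ", "))
  }
  as.integer(rowSums(m))
}

#' Fit the linear QI trend over storage time
#'
#' Ordinary least squares of mean QI on storage day; the slope is the QI
#' deterioration rate in demerit points per day.
#'
#' @param series a `qi_series` (from [aggregate_qi()]) or any data.frame with
#'   `storage_day` and `mean_qi` columns.
#' @return object of class `qi_trend`: list with `slope`, `intercept`,
#'   `r_squared` and the underlying `lm` fit.
#' @export
fit_qi_trend <- function(series) {
  if (!all(c("storage_day", "mean_qi") %in% names(series)))
    stop("series must have storage_day and mean_qi columns")
  if (length(unique(series$storage_day)) < 2L)
    stop("need at least 2 distinct storage days to fit a trend")
  fit <- stats::lm(mean_qi ~ storage_day, data = series)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((series$mean_qi - mean(series$mean_qi))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, model = fit),
    class = "qi_trend"
  )
}

#' Rejection QI of a panel
#'
#' The rejection threshold is the lowest total QI at which any judge assessed
#' a fillet as unacceptable for consumption; it is computed on raw per-record
#' QI values, not day means.
#'
#' @inheritParams aggregate_qi
#' @return integer rejection QI.
#' @export
rejection_threshold <- function(evaluations, scheme) {
  if (!"acceptable" %in% names(evaluations))
    stop("evaluations lack an acceptable column")
  qi <- evaluation_qi(evaluations, scheme)
  rejected <- !as.logical(evaluations$acceptable)
  if (!any(rejected))
    stop("no evaluation was flagged unacceptable; rejection QI undeterminable")
  min(qi[rejected])
}

#' Shelf life from a QI trend and a rejection threshold
#'
#' Solves `rejection_qi = intercept + slope * t` for the crossing time and
#' floors it to whole days: a fillet whose QI crosses the threshold during day
#' t+1 was last acceptable on day floor(t).
#'
#' @param fit a `qi_trend` object (or list with `slope` and `intercept`).
#' @param rejection_qi the rejection threshold in demerit points.
#' @return object of class `shelf_life`: list with `rejection_qi`,
#'   `crossing_time` (days, real) and `shelf_life_days` (integer).
#' @export
shelf_life_days <- function(fit, rejection_qi) {
  slope <- fit$slope; intercept <- fit$intercept
  if (!is.finite(slope) || slope <= 0)
    stop("non-positive slope: QI does not deteriorate, shelf life undefined")
  if (rejection_qi < intercept)
    stop("rejection QI below the fitted intercept; threshold already crossed at day 0")
  crossing <- (rejection_qi - intercept) / slope
  structure(
    list(rejection_qi = rejection_qi, crossing_time = crossing,
         shelf_life_days = as.integer(floor(crossing))),
    class = "shelf_life"
  )
}

#' Percent shelf-life extension
#'
#' @param reference_days shelf life of the reference (untreated) batch, days.
#' @param treated_days shelf life of the treated batch, days.
#' @return integer percent extension, rounded half-up (e.g. 28.57 -> 29).
#' @export
extension_percent <- function(reference_days, treated_days) {
  if (reference_days <= 0) stop("reference shelf life must be positive")
  pct <- 100 * (treated_days - reference_days) / reference_days
  # round half away from zero, so 28.57 -> 29 (R's round() is half-to-even)
  as.integer(sign(pct) * floor(abs(pct) + 0.5))
}
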