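# Residual z-scoring and outlier flagging per sensor/trial, plus tabular
# summaries of raw data and residuals.

#' Wrap externally computed residuals for z-scoring
#'
#' Builds a minimal decomposition object around a bare residual vector so
#' that [zscore_outliers()] can score residuals that were not produced by
#' the package's own decompositions (e.g. reference data or simulation
#' studies of the flagging rule itself). The coalesced series is taken to be
#' the residuals over a synthetic minute grid.
#'
#' @param residuals Numeric residual vector.
#' @param sensor_id,trial_id Labels for the group.
#' @param start Grid start (POSIXct or string).
#' @return A `decomposition` with `method = "external"`.
#' @export
residual_decomposition <- function(residuals, sensor_id = "external",
                                   trial_id = "T1",
                                   start = "2021-01-04T00:00:00") {
  residuals <- as.numeric(residuals)
  n <- length(residuals)
  if (n == 0L) stop("empty residuals")
  start <- as_naive_time(start)
  structure(
    list(method = "external", sensor_id = sensor_id, trial_id = trial_id,
         timestamps = minute_grid(start, start + n * 60),
         coalesced = residuals, seasonal = rep(0, n),
         trend = rep(NA_real_, n), residuals = residuals,
         filled = rep(FALSE, n), surrogate = NULL),
    class = "decomposition"
  )
}

#' Two-sided standard-normal critical value
#'
#' The threshold for the outlier rule: the `1 - alpha/2` quantile of the
#' standard normal. At the default significance level `alpha = 0.001` this is
#' 3.2905 (displayed as 3.29); at 0.05 it is 1.96.
#'
#' @param alpha Significance level in (0, 1).
#' @return The critical value (full precision; never pre-rounded).
#' @export
critical_z <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)")
  }
  stats::qnorm(1 - alpha / 2)
}

#' Outlier-detection configuration
#'
#' @param alpha Significance level in (0, 1); default 0.001.
#' @param strict If `TRUE` (default) flag `|z| > threshold`; if `FALSE` flag
#'   `|z| >= threshold`. The strict form follows the rule's primary
#'   statement; the non-strict form is exposed because summary tables
#'   elsewhere describe the count as `>=`.
#' @return An object of class `outlier_config`.
#' @export
outlier_config <- function(alpha = 0.001, strict = TRUE) {
  threshold <- critical_z(alpha)  # validates alpha
  structure(list(alpha = alpha, strict = isTRUE(strict),
                 threshold = threshold),
            class = "outlier_config")
}

#' Z-score residuals and flag outliers
#'
#' Standardizes the residuals of one sensor/trial decomposition with their
#' own sample mean and sample standard deviation (n-1 denominator) and flags
#' rows whose `|z|` exceeds the critical value at `cfg$alpha`. For the
#' standard additive method, edge rows with undefined trend are dropped
#' before scoring. Surrogate-imputed rows are retained (their residual is 0
#' under the alternative method, so their z is `-mean/sd` and they are
#' effectively never flagged when the residual mean is near 0).
#'
#' @param result A `decomposition` from [alt_decompose()] or
#'   [standard_additive_decompose()].
#' @param cfg An [outlier_config()].
#' @param degenerate What to do when the residual sd is (numerically) zero,
#'   as on a noiseless series: `"error"` (default) aborts; `"zero"` returns
#'   a table with all z = 0 and no flags. Numerically zero means
#'   `sd <= 1e-9 * max(1, |mean|)`, so that float jitter in an otherwise
#'   exact decomposition cannot masquerade as signal.
#' @return An `outlier_table`: a data.frame with columns `timestamp,
#'   sensor_id, trial_id, residual, z, is_outlier, filled` and attributes
#'   `residual_mean`, `residual_sd`, `threshold`, `alpha`, `method`.
#' @export
zscore_outliers <- function(result, cfg = outlier_config(),
                            degenerate = c("error", "zero")) {
  degenerate <- match.arg(degenerate)
  stopifnot(inherits(result, "decomposition"),
            inherits(cfg, "outlier_config"))
  if (is.null(result$residuals)) {
    stop("decomposition has no residuals; run alt_decompose() or ",
         "standard_additive_decompose() first")
  }
  keep <- !is.na(result$residuals)
  r <- result$residuals[keep]
  n <- length(r)
  if (n < 2L) stop("need at least 2 residuals")
  m <- mean(r)
  s <- stats::sd(r)
  if (s <= 1e-9 * max(1, abs(m))) {
    if (degenerate == "error") stop("degenerate residuals: sd = 0")
    z <- numeric(n)
    flag <- logical(n)
  } else {
    z <- (r - m) / s
    flag <- if (cfg$strict) abs(z) > cfg$threshold else
      abs(z) >= cfg$threshold
  }
  out <- data.frame(
    timestamp = result$timestamps[keep],
    sensor_id = result$sensor_id,
    trial_id = result$trial_id,
    residual = r,
    z = z,
    is_outlier = flag,
    filled = result$filled[keep],
    stringsAsFactors = FALSE
  )
  structure(out,
            residual_mean = m, residual_sd = s,
            threshold = cfg$threshold, alpha = cfg$alpha,
            method = result$method,
            class = c("outlier_table", "data.frame"))
}

#' Summarize residuals and outlier counts per sensor/trial/method
#'
#' One row per outlier table: residual mean and sd, outlier count, row count,
#' and (when the matching raw series is supplied) the raw missing-value
#' count.
#'
#' @param tables A single `outlier_table` or a list of them.
#' @param raw Optional [sensor_series()] or list of them (pre-coalescing);
#'   matched to tables by sensor and trial id for the `na_count_raw` column.
#' @return A data.frame with columns `sensor_id, trial_id, method, mean, sd,
#'   outlier_count, n, na_count_raw`.
#' @export
summarize_residuals <- function(tables, raw = NULL) {
  if (inherits(tables, "outlier_table")) tables <- list(tables)
  if (!is.null(raw) && inherits(raw, "sensor_series")) raw <- list(raw)
  na_lookup <- if (is.null(raw)) NULL else {
    stats::setNames(
      vapply(raw, function(s) sum(is.na(s$values)), integer(1)),
      vapply(raw, function(s) paste(s$sensor_id, s$trial_id), character(1)))
  }
  rows <- lapply(tables, function(tb) {
    key <- paste(tb$sensor_id[1L], tb$trial_id[1L])
    data.frame(
      sensor_id = tb$sensor_id[1L],
      trial_id = tb$trial_id[1L],
      method = attr(tb, "method"),
      mean = attr(tb, "residual_mean"),
      sd = attr(tb, "residual_sd"),
      outlier_count = sum(tb$is_outlier),
      n = nrow(tb),
      na_count_raw = if (is.null(na_lookup)) NA_integer_ else
        unname(na_lookup[key]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Descriptive statistics of raw sensor data
#'
#' One row per series: mean, median, sd, min, max over observed values and
#' the count of missing minutes.
#'
#' @param series_list A [sensor_series()] or list of them.
#' @return A data.frame with columns `sensor_id, trial_id, mean, median, sd,
#'   min, max, na_count`.
#' @export
summarize_raw <- function(series_list) {
  if (inherits(series_list, "sensor_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    v <- s$values[!is.na(s$values)]
    data.frame(
      sensor_id = s$sensor_id, trial_id = s$trial_id,
      mean = mean(v), median = stats::median(v), sd = stats::sd(v),
      min = min(v), max = max(v), na_count = sum(is.na(s$values)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
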