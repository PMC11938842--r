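# Median diurnal surrogate profile, missing-data coalescing, and the two
# decompositions (surrogate-subtraction "alternative" vs classical additive).

#' Build the median diurnal surrogate profile
#'
#' For every one of the 1440 hh:mm slots of the day, the surrogate value is
#' the median of all non-missing observations at that slot across the whole
#' trial. Even-count medians are the mean of the two central order
#' statistics. Slots with zero support (every day missing at that hh:mm) are
#' filled by circular linear interpolation between the nearest supported
#' slots; `support` records the number of contributing observations per slot
#' so interpolated slots are identifiable (support 0).
#'
#' The surrogate is always computed from the raw (pre-coalescing) series:
#' imputed values never feed back into the medians.
#'
#' @param series A [sensor_series()] spanning at least one full day.
#' @return An object of class `surrogate_profile` with fields `sensor_id`,
#'   `trial_id`, `slots` (1440 values) and `support` (1440 counts).
#' @export
build_surrogate <- function(series) {
  stopifnot(inherits(series, "sensor_series"))
  if (length(series$values) < 1440L) {
    stop("series must span at least one full day")
  }
  if (all(is.na(series$values))) stop("no surrogate support")
  slot <- slot_of_day(series$timestamps)
  ok <- !is.na(series$values)
  med <- rep(NA_real_, 1440L)
  sup <- integer(1440L)
  grp <- split(series$values[ok], slot[ok])
  idx <- as.integer(names(grp))
  med[idx] <- vapply(grp, stats::median, numeric(1))
  sup[idx] <- lengths(grp)
  if (anyNA(med)) med <- interpolate_circular(med)
  structure(
    list(sensor_id = series$sensor_id, trial_id = series$trial_id,
         slots = med, support = sup),
    class = "surrogate_profile"
  )
}

#' @export
print.surrogate_profile <- function(x, ...) {
  cat(sprintf(
    "<surrogate_profile> %s / %s: range [%.3f, %.3f] degC, %d zero-support slots\n",
    x$sensor_id, x$trial_id, min(x$slots), max(x$slots), sum(x$support == 0L)))
  invisible(x)
}

# Circular linear interpolation across the 1440-slot day for NA slots.
interpolate_circular <- function(v) {
  n <- length(v)
  known <- which(!is.na(v))
  if (length(known) == 0L) stop("no surrogate support")
  # unwrap onto a tripled axis so interpolation wraps midnight
  x <- c(known - n, known, known + n)
  y <- rep(v[known], 3L)
  miss <- which(is.na(v))
  v[miss] <- stats::approx(x, y, xout = miss)$y
  v
}

#' Replace missing values with the surrogate (coalescing)
#'
#' Every missing minute is filled with the surrogate value at the matching
#' hh:mm slot; observed values pass through unchanged. The result carries a
#' `filled` mask marking exactly the imputed minutes.
#'
#' @param series A [sensor_series()].
#' @param surrogate A [surrogate_profile()] built from the same sensor/trial.
#' @return An object of class `decomposition` with fields `coalesced` and
#'   `filled` (and `method = "coalesced"`); feed it to [alt_decompose()] or
#'   [standard_additive_decompose()].
#' @export
coalesce <- function(series, surrogate) {
  stopifnot(inherits(series, "sensor_series"),
            inherits(surrogate, "surrogate_profile"))
  if (!identical(series$sensor_id, surrogate$sensor_id) ||
      !identical(series$trial_id, surrogate$trial_id)) {
    stop("surrogate was built for ", surrogate$sensor_id, "/",
         surrogate$trial_id, ", not ", series$sensor_id, "/", series$trial_id)
  }
  filled <- is.na(series$values)
  vals <- series$values
  slot <- slot_of_day(series$timestamps)
  vals[filled] <- surrogate$slots[slot[filled]]
  structure(
    list(method = "coalesced",
         sensor_id = series$sensor_id, trial_id = series$trial_id,
         timestamps = series$timestamps,
         coalesced = vals, seasonal = NULL, trend = NULL, residuals = NULL,
         filled = filled, surrogate = surrogate),
    class = "decomposition"
  )
}

#' Alternative decomposition: subtract the tiled surrogate
#'
#' De-seasonalizes the coalesced series by subtracting the surrogate profile
#' tiled across days: `seasonal(t) = surrogate[hh:mm(t)]` and
#' `residual(t) = coalesced(t) - seasonal(t)`. There is no trend component.
#' The additive identity `coalesced = seasonal + residual` holds exactly at
#' every minute, and imputed minutes have residual exactly 0 by construction
#' (their value *is* the surrogate).
#'
#' @param coalesced A `decomposition` from [coalesce()].
#' @param surrogate Optional [surrogate_profile()]; defaults to the one the
#'   coalescing used.
#' @return A `decomposition` with `method = "alternative"`.
#' @export
alt_decompose <- function(coalesced, surrogate = NULL) {
  stopifnot(inherits(coalesced, "decomposition"))
  if (is.null(surrogate)) surrogate <- coalesced$surrogate
  stopifnot(inherits(surrogate, "surrogate_profile"))
  seasonal <- surrogate$slots[slot_of_day(coalesced$timestamps)]
  res <- coalesced$coalesced - seasonal
  res[coalesced$filled] <- 0  # identical subtraction, pinned exactly
  out <- coalesced
  out$method <- "alternative"
  out$seasonal <- seasonal
  out$trend <- rep(NA_real_, length(seasonal))
  out$residuals <- res
  out
}

#' Classical additive decomposition
#'
#' Textbook moving-average additive decomposition
#' `x = trend + seasonal + residual`:
#' the trend is a centered moving average over one period (split end-weights
#' for an even period), the seasonal figure is the per-slot mean of the
#' detrended series centered to zero mean over one period and tiled, and the
#' residual is the remainder. Trend and residual are undefined (NA) within
#' half a period of either edge. Matches `stats::decompose()`.
#'
#' @param coalesced A `decomposition` from [coalesce()] (no missing values),
#'   or a [sensor_series()] without missing values.
#' @param period Samples per season; 1440 for the daily cycle on a minute
#'   grid.
#' @return A `decomposition` with `method = "standard_additive"`.
#' @export
standard_additive_decompose <- function(coalesced, period = 1440L) {
  if (inherits(coalesced, "sensor_series")) {
    if (anyNA(coalesced$values)) {
      stop("series has missing values; coalesce() first")
    }
    coalesced <- structure(
      list(method = "coalesced", sensor_id = coalesced$sensor_id,
           trial_id = coalesced$trial_id, timestamps = coalesced$timestamps,
           coalesced = coalesced$values, seasonal = NULL, trend = NULL,
           residuals = NULL, filled = rep(FALSE, length(coalesced$values)),
           surrogate = NULL),
      class = "decomposition")
  }
  stopifnot(inherits(coalesced, "decomposition"))
  x <- coalesced$coalesced
  n <- length(x)
  period <- as.integer(period)
  if (n < 2L * period) stop("series shorter than 2 periods")
  trend <- centered_ma(x, period)
  detr <- x - trend
  # seasonal figure: per-slot mean of detrended values, centered to zero mean
  phase <- ((seq_len(n) - 1L) %% period) + 1L
  fig <- vapply(split(detr, phase),
                function(v) mean(v, na.rm = TRUE), numeric(1))
  fig <- fig[order(as.integer(names(fig)))]
  fig <- fig - mean(fig)
  seasonal <- fig[phase]
  res <- x - trend - seasonal
  out <- coalesced
  out$method <- "standard_additive"
  out$seasonal <- unname(seasonal)
  out$trend <- trend
  out$residuals <- unname(res)
  out
}

# Centered moving average of window `period`; for even periods the two outer
# weights are halved (weights (0.5, 1, ..., 1, 0.5)/period). NA within
# floor(period/2) of either edge.
centered_ma <- function(x, period) {
  if (period %% 2L == 0L) {
    w <- c(0.5, rep(1, period - 1L), 0.5) / period
  } else {
    w <- rep(1 / period, period)
  }
  as.numeric(stats::filter(x, w, sides = 2))
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition method=%s> %s / %s: %d minutes, %d imputed\n",
              x$method, x$sensor_id, x$trial_id, length(x$coalesced),
              sum(x$filled)))
  invisible(x)
}

#' Decomposition result as a tidy data frame
#'
#' Columns: `timestamp, sensor_id, trial_id, coalesced, seasonal, trend,
#' residual, filled`.
#'
#' @param x A `decomposition`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (ignored).
#' @return A data.frame, one row per minute.
#' @export
as.data.frame.decomposition <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  n <- length(x$coalesced)
  data.frame(
    timestamp = format_ts(x$timestamps),
    sensor_id = x$sensor_id, trial_id = x$trial_id,
    coalesced = x$coalesced,
    seasonal = if (is.null(x$seasonal)) rep(NA_real_, n) else x$seasonal,
    trend = if (is.null(x$trend)) rep(NA_real_, n) else x$trend,
    residual = if (is.null(x$residuals)) rep(NA_real_, n) else x$residuals,
    filled = x$filled,
    stringsAsFactors = FALSE
  )
}
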