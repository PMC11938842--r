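# Canonical data model: minute-gridded sensor series, raw sub-minute
# readings, binary event logs, and trial configuration.

#' Construct a minute-gridded sensor series
#'
#' A `sensor_series` holds one sensor's air-temperature readings on a complete
#' regular 1-minute grid covering `[start, end)`. Missing observations are
#' represented by `NA` in `values`; the missing mask is always `is.na(values)`.
#' Timestamps are naive local clock time stored as POSIXct in UTC so that no
#' daylight-saving shifts can ever occur on the grid.
#'
#' @param sensor_id Sensor label, e.g. `"LC_Canopy_1"`.
#' @param trial_id Trial label, e.g. `"T1"`.
#' @param timestamps POSIXct vector, strictly increasing, minute resolution,
#'   covering a contiguous window with no gaps or duplicates.
#' @param values Numeric vector of temperatures in deg C; `NA` marks missing.
#'   Non-missing values must be finite.
#' @return An object of class `sensor_series`.
#' @export
sensor_series <- function(sensor_id, trial_id, timestamps, values) {
  stopifnot(length(sensor_id) == 1L, length(trial_id) == 1L)
  timestamps <- as_naive_time(timestamps)
  values <- as.numeric(values)
  if (length(timestamps) != length(values)) {
    stop("timestamps and values must have equal length")
  }
  if (length(timestamps) == 0L) stop("empty series")
  check_minute_grid(timestamps)
  bad <- !is.na(values) & !is.finite(values)
  if (any(bad)) {
    stop("non-finite value at ", format_ts(timestamps[which(bad)[1L]]))
  }
  structure(
    list(sensor_id = as.character(sensor_id),
         trial_id = as.character(trial_id),
         timestamps = timestamps,
         values = values),
    class = "sensor_series"
  )
}

#' @export
print.sensor_series <- function(x, ...) {
  cat(sprintf(
    "<sensor_series> %s / %s: %d minutes [%s .. %s], %d missing\n",
    x$sensor_id, x$trial_id, length(x$values),
    format_ts(x$timestamps[1L]), format_ts(x$timestamps[length(x$timestamps)]),
    sum(is.na(x$values))))
  invisible(x)
}

#' Missing mask of a sensor series
#'
#' @param series A [sensor_series()].
#' @return Logical vector, `TRUE` where the value is missing.
#' @export
missing_mask <- function(series) {
  stopifnot(inherits(series, "sensor_series"))
  is.na(series$values)
}

#' Raw sub-minute sensor readings
#'
#' Container for readings before minute averaging (e.g. 10-second cadence).
#' Timestamps may be irregular but must be non-decreasing; values must be
#' finite.
#'
#' @param sensor_id Sensor label.
#' @param timestamps POSIXct vector, non-decreasing.
#' @param values Numeric temperatures in deg C, all finite.
#' @return An object of class `raw_readings`.
#' @export
raw_readings <- function(sensor_id, timestamps, values) {
  stopifnot(length(sensor_id) == 1L)
  timestamps <- as_naive_time(timestamps)
  values <- as.numeric(values)
  if (length(timestamps) != length(values)) {
    stop("timestamps and values must have equal length")
  }
  if (is.unsorted(timestamps)) stop("raw timestamps must be non-decreasing")
  bad <- !is.finite(values)
  if (any(bad)) {
    stop("non-finite raw value at ", format_ts(timestamps[which(bad)[1L]]))
  }
  structure(
    list(sensor_id = as.character(sensor_id),
         timestamps = timestamps, values = values),
    class = "raw_readings"
  )
}

#' Binary event log for one channel
#'
#' Channels are `door` plus up to three person-presence buttons
#' (`person_1..person_3`). States are 0/1 and are normalized so that no two
#' consecutive entries carry the same state (the first of a repeated run
#' wins).
#'
#' @param channel One of `"door"`, `"person_1"`, `"person_2"`, `"person_3"`.
#' @param timestamps POSIXct vector, non-decreasing.
#' @param states Integer 0/1 states.
#' @return An object of class `event_log` (normalized).
#' @export
event_log <- function(channel, timestamps, states) {
  channel <- match.arg(channel, event_channels())
  timestamps <- as_naive_time(timestamps)
  states <- as.integer(states)
  if (length(timestamps) != length(states)) {
    stop("timestamps and states must have equal length")
  }
  if (any(!states %in% c(0L, 1L))) stop("state not in {0,1}")
  if (is.unsorted(timestamps)) stop("event timestamps must be non-decreasing")
  # collapse repeated identical consecutive states: keep the first of each run
  if (length(states) > 0L) {
    keep <- c(TRUE, states[-1L] != states[-length(states)])
    timestamps <- timestamps[keep]
    states <- states[keep]
  }
  structure(
    list(channel = channel, timestamps = timestamps, states = states),
    class = "event_log"
  )
}

event_channels <- function() c("door", "person_1", "person_2", "person_3")

#' Trial configuration
#'
#' Describes one temperature trial: day/night setpoints, photoperiod, and the
#' full data window plus the analysis sub-window (the first week of each
#' trial keeps uniform seedling conditions and is excluded from analysis).
#'
#' @param trial_id Trial label.
#' @param day_setpoint,night_setpoint Day / night air-temperature setpoints
#'   in deg C.
#' @param day_hours,night_hours Photoperiod split; must sum to 24.
#' @param window POSIXct length-2 `[start, end)` of the full trial.
#' @param analysis_window POSIXct length-2 `[start, end)`, a sub-window of
#'   `window` used for analysis. Defaults to `window`.
#' @param day_start_hour Local clock hour at which the day period begins
#'   (default 6, i.e. 06:00).
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(trial_id, day_setpoint, night_setpoint,
                         day_hours = 16.5, night_hours = 7.5,
                         window, analysis_window = window,
                         day_start_hour = 6) {
  if (abs(day_hours + night_hours - 24) > 1e-9) {
    stop("day_hours + night_hours must equal 24")
  }
  window <- as_naive_time(window)
  analysis_window <- as_naive_time(analysis_window)
  stopifnot(length(window) == 2L, length(analysis_window) == 2L)
  if (window[1L] >= window[2L]) stop("empty trial window")
  if (analysis_window[1L] < window[1L] || analysis_window[2L] > window[2L]) {
    stop("analysis_window must lie within window")
  }
  structure(
    list(trial_id = as.character(trial_id),
         day_setpoint = as.numeric(day_setpoint),
         night_setpoint = as.numeric(night_setpoint),
         day_hours = day_hours, night_hours = night_hours,
         window = window, analysis_window = analysis_window,
         day_start_hour = as.numeric(day_start_hour)),
    class = "trial_config"
  )
}

#' Average raw readings onto the minute grid
#'
#' Each output minute is the arithmetic mean of the raw readings whose
#' timestamp falls in the half-open bin `[minute, minute + 1min)`. Minutes
#' with no readings are marked missing. Readings outside `window` are
#' ignored. Partially filled minutes use the mean of the available readings.
#'
#' @param raw A [raw_readings()] object.
#' @param window POSIXct length-2 `[start, end)`; boundaries must be whole
#'   minutes.
#' @param trial_id Trial label to stamp on the result.
#' @return A [sensor_series()] covering `window` exactly.
#' @export
minute_average <- function(raw, window, trial_id = "T1") {
  stopifnot(inherits(raw, "raw_readings"))
  window <- as_naive_time(window)
  stopifnot(length(window) == 2L)
  if (window[1L] >= window[2L]) stop("empty window")
  if (any(as.numeric(window) %% 60 != 0)) {
    stop("window boundaries must be whole minutes")
  }
  grid <- minute_grid(window[1L], window[2L])
  n <- length(grid)
  secs <- as.numeric(raw$timestamps) - as.numeric(window[1L])
  inside <- secs >= 0 & secs < n * 60
  idx <- floor(secs[inside] / 60) + 1  # 1-based minute bin
  vals <- raw$values[inside]
  means <- rep(NA_real_, n)
  if (length(idx) > 0L) {
    sums <- rowsum(vals, idx)
    counts <- rowsum(rep(1, length(idx)), idx)
    bins <- as.integer(rownames(sums))
    means[bins] <- sums[, 1L] / counts[, 1L]
  }
  sensor_series(raw$sensor_id, trial_id, grid, means)
}

#' Build a minute grid over a half-open window
#'
#' @param start,end POSIXct window boundaries; `end` exclusive.
#' @return POSIXct vector of minute instants covering `[start, end)`.
#' @export
minute_grid <- function(start, end) {
  start <- as_naive_time(start)
  end <- as_naive_time(end)
  if (start >= end) stop("empty window")
  seq(from = start, to = end - 60, by = 60)
}

#' Minute-of-day slot indices (1..1440)
#'
#' Maps each timestamp to its hh:mm slot, 1-based: 00:00 -> 1, 23:59 -> 1440.
#'
#' @param timestamps POSIXct vector.
#' @return Integer vector in 1..1440.
#' @export
slot_of_day <- function(timestamps) {
  timestamps <- as_naive_time(timestamps)
  (as.integer(as.numeric(timestamps) / 60) %% 1440L) + 1L
}

# ---- internal helpers -------------------------------------------------------

# Naive local clock time: parse/coerce into POSIXct pinned to UTC so the grid
# can never hit a DST fold. Accepts POSIXct, Date, or ISO-8601 strings.
as_naive_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(as.character(x), tz = "UTC"))
  }
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  if (anyNA(out) && !anyNA(x)) {
    stop("unparseable timestamp: ", x[which(is.na(out))[1L]])
  }
  out
}

format_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

check_minute_grid <- function(timestamps) {
  s <- as.numeric(timestamps)
  if (any(s %% 60 != 0)) stop("timestamps must be at whole minutes")
  if (length(s) > 1L) {
    d <- diff(s)
    if (any(d <= 0)) stop("duplicate or decreasing timestamps on minute grid")
    if (any(d != 60)) stop("gap in minute grid: timestamps must be contiguous")
  }
  invisible(TRUE)
}

# Align sparse (timestamp, value) rows onto the full minute grid spanning
# them; unmatched grid minutes become missing.
align_to_grid <- function(timestamps, values, window = NULL) {
  if (is.null(window)) {
    window <- c(min(timestamps), max(timestamps) + 60)
  }
  grid <- minute_grid(window[1L], window[2L])
  out <- rep(NA_real_, length(grid))
  pos <- match(as.numeric(timestamps), as.numeric(grid))
  if (anyNA(pos)) {
    stop("timestamp outside grid window: ",
         format_ts(timestamps[which(is.na(pos))[1L]]))
  }
  out[pos] <- values
  list(timestamps = grid, values = out)
}
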