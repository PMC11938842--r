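# Agricultural operations (Agr.Ops): turn door / person-presence event logs
# into per-minute operation intensity and the cumulative covariate used by
# the stability regression.

#' Rasterize event logs onto the minute grid
#'
#' Converts normalized binary event logs into per-minute occupancy: a minute
#' counts as `door_open = 1` if the door is open for any part of it, and
#' `person_count` is the number of person channels in state 1 at the minute's
#' start (half-open presence intervals `[on, off)`). An unterminated final
#' "open"/"present" state is closed at the window end.
#'
#' @param logs A list of [event_log()] objects (any subset of the four
#'   channels).
#' @param window POSIXct length-2 `[start, end)` at whole minutes.
#' @return An `agrops_series` data.frame with columns `timestamp,
#'   person_count, door_open, intensity, cumulative` (the last two `NA` until
#'   [cumulative_agr_ops()] is applied).
#' @export
events_to_minutes <- function(logs, window) {
  window <- as_naive_time(window)
  stopifnot(length(window) == 2L)
  if (any(as.numeric(window) %% 60 != 0)) {
    stop("window boundaries must be whole minutes")
  }
  grid <- minute_grid(window[1L], window[2L])
  n <- length(grid)
  person <- integer(n)
  door <- integer(n)
  for (l in logs) {
    stopifnot(inherits(l, "event_log"))
    iv <- log_intervals(l, window)
    if (nrow(iv) == 0L) next
    if (l$channel == "door") {
      # open during any part of the minute: [on, off) meets [t, t+60)
      for (j in seq_len(nrow(iv))) {
        first <- floor((iv$on[j] - as.numeric(window[1L])) / 60) + 1
        last <- ceiling((iv$off[j] - as.numeric(window[1L])) / 60)
        first <- max(1, first)
        last <- min(n, last)
        if (last >= first) door[first:last] <- 1L
      }
    } else {
      # present at the minute's start: on <= t < off
      for (j in seq_len(nrow(iv))) {
        o <- (iv$on[j] - as.numeric(window[1L])) / 60
        first <- if (o == floor(o)) o + 1 else ceiling(o) + 1
        last <- ceiling((iv$off[j] - as.numeric(window[1L])) / 60)
        first <- max(1, first)
        last <- min(n, last)
        if (last >= first) person[first:last] <- person[first:last] + 1L
      }
    }
  }
  if (any(person > 3L)) stop("person_count exceeds 3: overlapping duplicate intervals")
  structure(
    data.frame(timestamp = grid, person_count = person, door_open = door,
               intensity = NA_real_, cumulative = NA_real_),
    weights = NULL,
    class = c("agrops_series", "data.frame")
  )
}

# "On" intervals [on, off) in epoch seconds for one normalized log, clipped
# to the window; an unterminated final on-state closes at window end.
log_intervals <- function(l, window) {
  ts <- as.numeric(l$timestamps)
  st <- l$states
  if (length(st) > 0L && st[1L] == 0L) {  # leading "off" is a no-op
    ts <- ts[-1L]
    st <- st[-1L]
  }
  # normalized logs alternate 1,0,1,0,... so ons/offs pair positionally
  on <- ts[st == 1L]
  off <- ts[st == 0L]
  if (length(on) > length(off)) {
    off <- c(off, as.numeric(window[2L]))
  }
  iv <- data.frame(on = on, off = off)
  iv <- iv[iv$off > as.numeric(window[1L]) & iv$on < as.numeric(window[2L]), ,
           drop = FALSE]
  iv$on <- pmax(iv$on, as.numeric(window[1L]))
  iv$off <- pmin(iv$off, as.numeric(window[2L]))
  iv
}

#' Cumulative Agr.Ops covariate
#'
#' Per-minute operation intensity is a weighted sum of occupancy
#' (`weights["person"] * person_count + weights["door"] * door_open`); the
#' cumulative covariate is its running sum from the window start. The
#' default weights (person 1, door 0) measure person-minutes with
#' multiplicity: three simultaneous people count three-fold, and the door
#' does not enter the covariate. Both weights are configurable and recorded
#' on the result.
#'
#' @param series An `agrops_series` from [events_to_minutes()].
#' @param weights Named numeric `c(person = 1, door = 0)`; non-negative.
#' @return The series with `intensity` and `cumulative` filled in and the
#'   weights stored in the `weights` attribute.
#' @export
cumulative_agr_ops <- function(series, weights = c(person = 1, door = 0)) {
  stopifnot(inherits(series, "agrops_series"))
  if (!all(c("person", "door") %in% names(weights))) {
    stop("weights must name 'person' and 'door'")
  }
  if (any(weights < 0)) stop("weights must be non-negative")
  series$intensity <- weights[["person"]] * series$person_count +
    weights[["door"]] * series$door_open
  series$cumulative <- cumsum(series$intensity)
  attr(series, "weights") <- weights
  series
}

#' Write an Agr.Ops series to CSV
#'
#' @param series An `agrops_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_agrops <- function(series, path) {
  df <- as.data.frame(series)
  df$timestamp <- format_ts(df$timestamp)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
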