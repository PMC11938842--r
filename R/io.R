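# CSV readers/writers for the two log dialects and tidy result tables.
#
# sensor CSV: timestamp,sensor_id,value_c   (ISO-8601, e.g. 2021-03-01T08:00:00)
# event  CSV: timestamp,channel,state

#' Read a long-format sensor log
#'
#' Parses `timestamp,sensor_id,value_c` rows, partitions them by sensor, and
#' aligns each sensor onto a complete minute grid; minutes absent from the
#' file become missing. Duplicate (sensor, timestamp) rows are an error.
#'
#' @param path CSV file path.
#' @param window Optional POSIXct length-2 `[start, end)` grid window; by
#'   default each sensor spans its own first to last observed minute.
#' @param trial_id Trial label to stamp on the series.
#' @return Named list of [sensor_series()], one per sensor_id.
#' @export
read_sensor_log <- function(path, window = NULL, trial_id = "T1") {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("timestamp", "sensor_id", "value_c")
  if (!identical(names(df), need)) {
    stop("unknown columns: expected header ", paste(need, collapse = ","),
         " but found ", paste(names(df), collapse = ","))
  }
  ts <- parse_iso_or_die(df$timestamp)
  val <- suppressWarnings(as.numeric(df$value_c))
  bad <- is.na(val) & !(df$value_c %in% c("", "NA"))
  if (any(bad)) {
    stop("unparseable value_c at row ", which(bad)[1L])
  }
  val[df$value_c %in% c("", "NA")] <- NA_real_
  key <- paste(df$sensor_id, df$timestamp)
  if (anyDuplicated(key)) {
    stop("duplicate (sensor, timestamp) row at row ",
         which(duplicated(key))[1L])
  }
  out <- list()
  for (sid in unique(df$sensor_id)) {
    sel <- df$sensor_id == sid
    al <- align_to_grid(ts[sel], val[sel], window)
    out[[sid]] <- sensor_series(sid, trial_id, al$timestamps, al$values)
  }
  out
}

#' Write sensor series to a long-format sensor log
#'
#' Missing values are written as empty fields and round-trip back to missing.
#'
#' @param series_list A [sensor_series()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensor_log <- function(series_list, path) {
  if (inherits(series_list, "sensor_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    data.frame(timestamp = format_ts(s$timestamps),
               sensor_id = s$sensor_id,
               value_c = ifelse(is.na(s$values), "",
                                format(s$values, digits = 17, trim = TRUE,
                                       scientific = FALSE)),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a binary event log
#'
#' Parses `timestamp,channel,state` rows into one normalized [event_log()]
#' per channel. Repeated identical consecutive states collapse to the first
#' occurrence. Channels with no rows are returned as permanently-0 logs.
#'
#' @param path CSV file path.
#' @return Named list of [event_log()], one per channel in
#'   `door, person_1, person_2, person_3`.
#' @export
read_event_log <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("timestamp", "channel", "state")
  if (!identical(names(df), need)) {
    stop("unknown columns: expected header ", paste(need, collapse = ","),
         " but found ", paste(names(df), collapse = ","))
  }
  out <- list()
  if (nrow(df) == 0L) {
    for (ch in event_channels()) {
      out[[ch]] <- event_log(ch, as_naive_time(character(0)), integer(0))
    }
    return(out)
  }
  ts <- parse_iso_or_die(df$timestamp)
  if (any(!df$state %in% c("0", "1"))) {
    stop("state not in {0,1} at row ", which(!df$state %in% c("0", "1"))[1L])
  }
  if (any(!df$channel %in% event_channels())) {
    stop("unknown channel at row ",
         which(!df$channel %in% event_channels())[1L])
  }
  for (ch in event_channels()) {
    sel <- df$channel == ch
    o <- order(ts[sel])
    out[[ch]] <- event_log(ch, ts[sel][o], as.integer(df$state[sel][o]))
  }
  out
}

#' Write event logs to CSV
#'
#' @param logs A list of [event_log()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(logs, path) {
  rows <- lapply(logs, function(l) {
    if (length(l$timestamps) == 0L) return(NULL)
    data.frame(timestamp = format_ts(l$timestamps), channel = l$channel,
               state = l$states, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(timestamp = character(0), channel = character(0),
               state = integer(0))
  if (nrow(df)) df <- df[order(df$timestamp, df$channel), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_iso_or_die <- function(x) {
  ts <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  na <- is.na(ts)
  if (any(na)) {  # tolerate a space separator
    ts[na] <- as.POSIXct(strptime(x[na], "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  }
  if (anyNA(ts)) stop("unparseable timestamp at row ", which(is.na(ts))[1L])
  ts
}
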