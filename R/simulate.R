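# Deterministic seeded growth-chamber simulator: diurnal square-wave air
# temperature with exponential-approach transitions, per-sensor bias and
# noise, block missingness, routine agricultural operations, and planted
# anomalies with ground-truth labels.

#' Default four-trial plan
#'
#' Four sequential 35-day trials with day setpoints 30/24/28/26 deg C,
#' night setpoints 6 deg C below day, a 16.5 h day / 7.5 h night photoperiod
#' starting at 06:00, and a 28-day analysis window that drops the first week
#' (uniform seedling conditions).
#'
#' @param start POSIXct or string; start of the first trial window.
#' @return List of four [trial_config()] objects named T1..T4.
#' @export
default_trial_plan <- function(start = "2021-01-04T00:00:00") {
  start <- as_naive_time(start)
  day_sp <- c(T1 = 30, T2 = 24, T3 = 28, T4 = 26)
  lapply(stats::setNames(seq_along(day_sp), names(day_sp)), function(k) {
    w0 <- start + (k - 1) * 35 * 86400
    trial_config(names(day_sp)[k],
                 day_setpoint = day_sp[[k]],
                 night_setpoint = day_sp[[k]] - 6,
                 window = c(w0, w0 + 35 * 86400),
                 analysis_window = c(w0 + 7 * 86400, w0 + 35 * 86400))
  })
}

#' Default sensor roster
#'
#' Three low-cost sensors plus the reference logger, with small location
#' biases, Gaussian noise levels on the order of the study's residual
#' standard deviations, and a 12-minute air-conditioning response lag.
#'
#' @return Data.frame with columns `sensor_id, bias, noise_sd,
#'   transition_lag`.
#' @export
default_sensors <- function() {
  data.frame(
    sensor_id = c("LC_Canopy_1", "LC_Canopy_2", "LC_Reference", "Reference"),
    bias = c(1.0, -0.8, 0.0, 0.0),
    noise_sd = c(0.4, 0.4, 0.4, 0.15),
    transition_lag = c(12, 12, 12, 12),
    stringsAsFactors = FALSE
  )
}

#' Planted anomaly event
#'
#' Presets mirror the chamber's uncertainty taxonomy: door and occupancy
#' temperature bumps (with matching event-log entries), slow sensor drift,
#' power outages (block missingness), one-minute power-surge spikes, and
#' air-conditioning response delays at the day/night transitions.
#'
#' @param kind One of `door_bump`, `occupancy_bump`, `sensor_drift`,
#'   `power_outage`, `power_surge_spike`, `ac_delay`.
#' @param start POSIXct or string; event start (whole minute).
#' @param duration_min Duration in minutes (a `power_surge_spike` always
#'   lasts one minute).
#' @param magnitude Deg C for temperature effects; minutes of extra lag for
#'   `ac_delay`.
#' @param sensors Character vector of affected sensor ids, or `NULL` for all.
#' @param person_channel Person button pressed for `occupancy_bump`
#'   (1, 2 or 3).
#' @return An object of class `anomaly_event`.
#' @export
anomaly_event <- function(kind, start, duration_min, magnitude,
                          sensors = NULL, person_channel = 2L) {
  kind <- match.arg(kind, c("door_bump", "occupancy_bump", "sensor_drift",
                            "power_outage", "power_surge_spike", "ac_delay"))
  if (kind == "power_surge_spike") duration_min <- 1L
  stopifnot(duration_min >= 1L, person_channel %in% 1:3)
  structure(
    list(kind = kind, start = as_naive_time(start),
         duration_min = as.integer(duration_min),
         magnitude = as.numeric(magnitude),
         sensors = sensors, person_channel = as.integer(person_channel)),
    class = "anomaly_event"
  )
}

#' Simulator configuration
#'
#' @param trials List of [trial_config()]; default [default_trial_plan()].
#' @param sensors Data.frame as from [default_sensors()].
#' @param anomalies List of [anomaly_event()] objects.
#' @param routine_ops List describing scheduled daily operations:
#'   `list(visit_start_hour, visit_minutes, door = TRUE)`. One person enters
#'   every day; set `visit_minutes = 0` to disable.
#' @param seed Integer master seed; all sensor noise streams derive from it
#'   via stable per-trial/per-sensor offsets, so adding a sensor does not
#'   perturb existing streams.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(trials = default_trial_plan(),
                       sensors = default_sensors(),
                       anomalies = list(),
                       routine_ops = list(visit_start_hour = 9,
                                          visit_minutes = 30, door = TRUE),
                       seed = 1L) {
  if (inherits(trials, "trial_config")) trials <- list(trials)
  stopifnot(all(vapply(trials, inherits, logical(1), "trial_config")),
            is.data.frame(sensors),
            all(c("sensor_id", "bias", "noise_sd", "transition_lag") %in%
                  names(sensors)),
            all(sensors$noise_sd >= 0), all(sensors$transition_lag >= 0))
  if (inherits(anomalies, "anomaly_event")) anomalies <- list(anomalies)
  names(trials) <- vapply(trials, `[[`, character(1), "trial_id")
  structure(
    list(trials = trials, sensors = sensors, anomalies = anomalies,
         routine_ops = routine_ops, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate chamber sensor streams, event logs and ground-truth labels
#'
#' The base signal is a square wave between the day and night setpoints on
#' the trial photoperiod, passed through an exponential-approach filter with
#' the sensor's response lag (time constant in minutes; 0 means instantaneous
#' steps). Per-sensor bias and iid Gaussian noise are added, anomalies are
#' superposed additively, power outages mask whole blocks as missing, and
#' door/person event logs are generated consistently with the routine
#' schedule and with door/occupancy anomalies.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `series` (list of [sensor_series()], one per
#'   sensor x trial, named `sensor/trial`), `events` (per trial: named list
#'   of [event_log()]), `labels` (data.frame `timestamp, sensor_id, trial_id,
#'   kind`, one row per planted anomalous minute), and `config`.
#' @export
simulate_chamber <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  series <- list()
  events <- list()
  labels <- list()
  for (tr in cfg$trials) {
    grid <- minute_grid(tr$window[1L], tr$window[2L])
    n <- length(grid)
    target_night <- rep(tr$night_setpoint, n)
    hour_of_day <- (as.numeric(grid) %% 86400) / 3600
    is_day <- hour_of_day >= tr$day_start_hour &
      hour_of_day < tr$day_start_hour + tr$day_hours
    anns <- Filter(function(a) {
      a$start >= tr$window[1L] && a$start < tr$window[2L]
    }, cfg$anomalies)
    for (i in seq_len(nrow(cfg$sensors))) {
      sid <- cfg$sensors$sensor_id[i]
      mine <- Filter(function(a) is.null(a$sensors) || sid %in% a$sensors,
                     anns)
      tau <- rep(cfg$sensors$transition_lag[i], n)
      for (a in mine) {
        if (a$kind == "ac_delay") {
          idx <- event_minutes(a, grid)
          tau[idx] <- tau[idx] + a$magnitude
        }
      }
      target <- ifelse(is_day, tr$day_setpoint, target_night)
      base <- lag_filter(target, tau)
      set.seed(stream_seed(cfg$seed, tr$trial_id, sid))
      noise <- if (cfg$sensors$noise_sd[i] > 0) {
        stats::rnorm(n, 0, cfg$sensors$noise_sd[i])
      } else numeric(n)
      vals <- base + cfg$sensors$bias[i] + noise
      miss <- rep(FALSE, n)
      for (a in mine) {
        idx <- event_minutes(a, grid)
        if (length(idx) == 0L) next
        vals[idx] <- vals[idx] + anomaly_effect(a, length(idx))
        if (a$kind == "power_outage") miss[idx] <- TRUE
        labels[[length(labels) + 1L]] <- data.frame(
          timestamp = grid[idx], sensor_id = sid, trial_id = tr$trial_id,
          kind = a$kind, stringsAsFactors = FALSE)
      }
      vals[miss] <- NA_real_
      series[[paste(sid, tr$trial_id, sep = "/")]] <-
        sensor_series(sid, tr$trial_id, grid, vals)
    }
    events[[tr$trial_id]] <- build_event_logs(cfg, tr)
  }
  labels <- if (length(labels)) do.call(rbind, labels) else
    data.frame(timestamp = as_naive_time(character(0)),
               sensor_id = character(0), trial_id = character(0),
               kind = character(0))
  list(series = series, events = events, labels = labels, config = cfg)
}

# minute indices covered by an anomaly event within a trial grid
event_minutes <- function(a, grid) {
  k0 <- match(as.numeric(a$start), as.numeric(grid))
  if (is.na(k0)) return(integer(0))
  k0:min(length(grid), k0 + a$duration_min - 1L)
}

# additive temperature effect of an anomaly over its own minutes
anomaly_effect <- function(a, len) {
  switch(a$kind,
         door_bump = ,
         occupancy_bump = rep(a$magnitude, len),
         sensor_drift = a$magnitude * seq_len(len) / len,
         power_surge_spike = rep(a$magnitude, len),
         power_outage = numeric(len),
         ac_delay = numeric(len))  # realized through the lag filter
}

# exponential approach toward a (possibly stepping) target with per-minute
# time constant tau (minutes); tau = 0 means instantaneous tracking
lag_filter <- function(target, tau) {
  n <- length(target)
  alpha <- ifelse(tau <= 0, 1, 1 - exp(-1 / tau))
  if (n == 0L) return(numeric(0))
  if (length(unique(alpha)) == 1L) {
    a <- alpha[1L]
    if (a == 1) return(target)
    out <- stats::filter(a * target, 1 - a, method = "recursive",
                         init = target[1L])
    return(as.numeric(out))
  }
  out <- numeric(n)
  out[1L] <- target[1L]
  for (k in 2:n) {
    out[k] <- out[k - 1L] + alpha[k] * (target[k] - out[k - 1L])
  }
  out
}

# stable substream seed: master seed plus a trial offset and a small hash of
# the sensor id, kept well inside 32-bit integer range
stream_seed <- function(seed, trial_id, sensor_id) {
  h <- sum(utf8ToInt(sensor_id) * seq_along(utf8ToInt(sensor_id))) %% 9973L
  t <- sum(utf8ToInt(trial_id)) %% 997L
  (abs(seed) %% 100000L) * 10000L + t * 10L + h %% 10L + h * 100L
}

# routine daily visits plus anomaly-driven door/occupancy intervals, merged
# per channel into alternating 1/0 logs
build_event_logs <- function(cfg, tr) {
  w0 <- as.numeric(tr$window[1L])
  w1 <- as.numeric(tr$window[2L])
  iv <- list(door = NULL, person_1 = NULL, person_2 = NULL, person_3 = NULL)
  add <- function(ch, on, off) {
    iv[[ch]] <<- rbind(iv[[ch]], data.frame(on = on, off = off))
  }
  ro <- cfg$routine_ops
  if (!is.null(ro) && ro$visit_minutes > 0) {
    days <- seq(w0, w1 - 1, by = 86400)
    on <- days + ro$visit_start_hour * 3600
    off <- on + ro$visit_minutes * 60
    add("person_1", on, pmin(off, w1))
    if (isTRUE(ro$door)) add("door", on, pmin(off, w1))
  }
  for (a in cfg$anomalies) {
    s <- as.numeric(a$start)
    if (s < w0 || s >= w1) next
    e <- min(s + a$duration_min * 60, w1)
    if (a$kind == "door_bump") add("door", s, e)
    if (a$kind == "occupancy_bump") {
      add(paste0("person_", a$person_channel), s, e)
      add("door", s, e)
    }
  }
  logs <- list()
  for (ch in event_channels()) {
    m <- merge_intervals(iv[[ch]])
    if (is.null(m) || nrow(m) == 0L) {
      logs[[ch]] <- event_log(ch, as_naive_time(character(0)), integer(0))
    } else {
      ts <- as_naive_time(as.POSIXct(
        as.vector(rbind(m$on, m$off)), origin = "1970-01-01", tz = "UTC"))
      logs[[ch]] <- event_log(ch, ts, rep(c(1L, 0L), nrow(m)))
    }
  }
  logs
}

merge_intervals <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(df)
  df <- df[order(df$on), , drop = FALSE]
  on <- df$on[1L]
  off <- df$off[1L]
  out <- list()
  for (j in seq_len(nrow(df))[-1L]) {
    if (df$on[j] <= off) {
      off <- max(off, df$off[j])
    } else {
      out[[length(out) + 1L]] <- c(on, off)
      on <- df$on[j]
      off <- df$off[j]
    }
  }
  out[[length(out) + 1L]] <- c(on, off)
  m <- do.call(rbind, out)
  data.frame(on = m[, 1L], off = m[, 2L])
}

#' Score detections against planted ground truth
#'
#' Joins the simulator's label table to an outlier table on (timestamp,
#' sensor) and reports per-kind recall (fraction of labelled minutes that
#' were flagged) and the false-flag rate on clean minutes. Labelled minutes
#' absent from the outlier table (e.g. outage minutes dropped or imputed)
#' count as misses for recall.
#'
#' @param labels Label data.frame from [simulate_chamber()].
#' @param tables A single `outlier_table` or list of them.
#' @return List with `per_kind` (data.frame `kind, planted, flagged,
#'   recall`), `recall` (overall, `NA` if nothing planted), and
#'   `false_flag_rate` (flagged fraction of unlabelled minutes).
#' @export
labels_to_truth <- function(labels, tables) {
  if (inherits(tables, "outlier_table")) tables <- list(tables)
  flat <- do.call(rbind, lapply(tables, function(tb) {
    data.frame(key = paste(as.numeric(tb$timestamp), tb$sensor_id),
               is_outlier = tb$is_outlier, stringsAsFactors = FALSE)
  }))
  lab_key <- if (nrow(labels)) {
    paste(as.numeric(labels$timestamp), labels$sensor_id)
  } else character(0)
  hit <- flat$is_outlier[match(lab_key, flat$key)]
  hit[is.na(hit)] <- FALSE  # labelled minute not scored -> missed
  per_kind <- if (nrow(labels)) {
    agg <- stats::aggregate(hit, by = list(kind = labels$kind),
                            FUN = function(v) c(sum(v), length(v)))
    data.frame(kind = agg$kind, planted = agg$x[, 2L], flagged = agg$x[, 1L],
               recall = agg$x[, 1L] / agg$x[, 2L], stringsAsFactors = FALSE)
  } else {
    data.frame(kind = character(0), planted = integer(0),
               flagged = integer(0), recall = numeric(0))
  }
  clean <- !(flat$key %in% lab_key)
  list(per_kind = per_kind,
       recall = if (length(hit)) mean(hit) else NA_real_,
       false_flag_rate = if (any(clean)) mean(flat$is_outlier[clean])
                         else NA_real_)
}
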