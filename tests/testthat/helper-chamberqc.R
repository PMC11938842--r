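# Shared fixture builders. Everything is generated in code; no files.

T0 <- as.POSIXct("2021-01-04 00:00:00", tz = "UTC")

# minute-gridded series of `days` full days starting at T0
mk_series <- function(values, sensor_id = "S1", trial_id = "T1",
                      start = T0) {
  grid <- minute_grid(start, start + length(values) * 60)
  sensor_series(sensor_id, trial_id, grid, values)
}

# noiseless square wave on the default photoperiod (day 06:00 + 16.5 h)
square_wave <- function(days, day = 30, night = 24, start = T0,
                        day_start_hour = 6, day_hours = 16.5) {
  grid <- minute_grid(start, start + days * 86400)
  hr <- (as.numeric(grid) %% 86400) / 3600
  ifelse(hr >= day_start_hour & hr < day_start_hour + day_hours, day, night)
}

# one-trial simulator config used across tests
small_sim <- function(days = 7, seed = 1, noise_sd = 0.4, lag = 0,
                      sensors = NULL, anomalies = list(),
                      analysis_skip_days = 0, routine_visit_minutes = 30) {
  tr <- trial_config("T1", 30, 24,
                     window = c(T0, T0 + days * 86400),
                     analysis_window = c(T0 + analysis_skip_days * 86400,
                                         T0 + days * 86400))
  if (is.null(sensors)) {
    sensors <- data.frame(sensor_id = "S1", bias = 0, noise_sd = noise_sd,
                          transition_lag = lag, stringsAsFactors = FALSE)
  }
  sim_config(trials = list(tr), sensors = sensors, anomalies = anomalies,
             routine_ops = list(visit_start_hour = 9,
                                visit_minutes = routine_visit_minutes,
                                door = TRUE),
             seed = seed)
}

# decomposition object wrapping bare residuals, for direct z-score tests
mk_resid_decomp <- function(residuals, sensor_id = "S1", trial_id = "T1",
                            filled = NULL) {
  d <- residual_decomposition(residuals, sensor_id, trial_id, start = T0)
  if (!is.null(filled)) d$filled <- filled
  d
}

# brute-force per-slot median oracle, independent of build_surrogate
oracle_slot_medians <- function(series) {
  slot <- (as.integer(as.numeric(series$timestamps) / 60) %% 1440L) + 1L
  out <- rep(NA_real_, 1440L)
  for (k in unique(slot)) {
    v <- series$values[slot == k]
    v <- v[!is.na(v)]
    if (length(v)) out[k] <- stats::median(v)
  }
  out
}
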