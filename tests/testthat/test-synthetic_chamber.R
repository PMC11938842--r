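# Seeded chamber simulator and ground-truth scoring.

test_that("simulation is deterministic under a fixed seed and varies across seeds", {
  a <- simulate_chamber(small_sim(days = 2, seed = 5))
  b <- simulate_chamber(small_sim(days = 2, seed = 5))
  expect_identical(a$series[["S1/T1"]]$values, b$series[["S1/T1"]]$values)
  expect_identical(a$events, b$events)
  c <- simulate_chamber(small_sim(days = 2, seed = 6))
  expect_false(identical(a$series[["S1/T1"]]$values,
                         c$series[["S1/T1"]]$values))
})

test_that("photoperiod puts 16.5/24 of each day at the day setpoint (zero lag, zero noise)", {
  sim <- simulate_chamber(small_sim(days = 4, noise_sd = 0, lag = 0))
  v <- sim$series[["S1/T1"]]$values
  expect_equal(mean(v == 30), 16.5 / 24)
  expect_equal(mean(v == 24), 7.5 / 24)
  expect_equal(mean(v == 30), 0.6875)
})

test_that("noiseless anomaly-free output gives residuals identically 0 end to end", {
  sim <- simulate_chamber(small_sim(days = 3, noise_sd = 0, lag = 15))
  s <- sim$series[["S1/T1"]]
  p <- build_surrogate(s)
  # every supported slot equals the (identical across days... after the
  # first-day transient) diurnal pattern; residuals vanish exactly
  d <- alt_decompose(coalesce(s, p))
  expect_lt(max(abs(d$residuals[1441:length(d$residuals)])), 1e-9)

  sim0 <- simulate_chamber(small_sim(days = 3, noise_sd = 0, lag = 0))
  s0 <- sim0$series[["S1/T1"]]
  d0 <- alt_decompose(coalesce(s0, build_surrogate(s0)))
  expect_true(all(d0$residuals == 0))
  # surrogate equals the noiseless wave exactly at every slot
  expect_identical(build_surrogate(s0)$slots, square_wave(1))
})

test_that("anomaly kinds are superposed as specified", {
  anns <- list(
    anomaly_event("power_surge_spike", "2021-01-05T10:00:00", 5, 9),
    anomaly_event("sensor_drift", "2021-01-06T00:00:00", 100, 2),
    anomaly_event("power_outage", "2021-01-07T02:00:00", 60, 0))
  sim <- simulate_chamber(small_sim(days = 5, noise_sd = 0, lag = 0,
                                    anomalies = anns))
  clean <- simulate_chamber(small_sim(days = 5, noise_sd = 0, lag = 0))
  v <- sim$series[["S1/T1"]]$values
  v0 <- clean$series[["S1/T1"]]$values
  g <- sim$series[["S1/T1"]]$timestamps
  spike_at <- which(g == as_naive_time("2021-01-05T10:00:00"))
  expect_equal(v[spike_at] - v0[spike_at], 9)
  expect_equal(sum(v != v0, na.rm = TRUE), 1 + 100)  # spike(1 min) + drift
  drift_end <- which(g == as_naive_time("2021-01-06T01:39:00"))
  expect_equal(v[drift_end] - v0[drift_end], 2)  # ramp reaches magnitude
  out_idx <- which(g >= as_naive_time("2021-01-07T02:00:00") &
                     g < as_naive_time("2021-01-07T03:00:00"))
  expect_true(all(is.na(v[out_idx])))
  # labels enumerate every anomalous minute with its kind
  expect_equal(sum(sim$labels$kind == "power_outage"), 60L)
  expect_equal(sum(sim$labels$kind == "sensor_drift"), 100L)
  expect_equal(sum(sim$labels$kind == "power_surge_spike"), 1L)
})

test_that("ac_delay slows the approach to the new setpoint", {
  ann <- anomaly_event("ac_delay", "2021-01-05T06:00:00", 120, 60)
  lagged <- simulate_chamber(small_sim(days = 3, noise_sd = 0, lag = 10,
                                       anomalies = list(ann)))
  normal <- simulate_chamber(small_sim(days = 3, noise_sd = 0, lag = 10))
  g <- normal$series[["S1/T1"]]$timestamps
  k <- which(g == as_naive_time("2021-01-05T06:30:00"))
  expect_lt(lagged$series[["S1/T1"]]$values[k],
            normal$series[["S1/T1"]]$values[k])
})

test_that("door and occupancy anomalies appear in the event logs", {
  anns <- list(
    anomaly_event("occupancy_bump", "2021-01-05T14:00:00", 20, 1.5,
                  person_channel = 2),
    anomaly_event("door_bump", "2021-01-06T07:00:00", 10, 1.0))
  sim <- simulate_chamber(small_sim(days = 4, anomalies = anns))
  ev <- sim$events$T1
  expect_equal(ev$person_2$states, c(1L, 0L))
  expect_equal(format_chk <- as.numeric(ev$person_2$timestamps[1]),
               as.numeric(as_naive_time("2021-01-05T14:00:00")))
  # door log carries the daily routine visits plus both anomaly intervals
  expect_equal(sum(ev$door$states == 1), 4 + 2)
  # routine person_1 visits: 30 min/day
  am <- cumulative_agr_ops(events_to_minutes(ev, sim$config$trials$T1$window))
  expect_equal(am$cumulative[nrow(am)], 4 * 30 + 20)
})

test_that("adding a sensor does not perturb existing noise streams", {
  one <- small_sim(days = 2, seed = 8)
  two <- small_sim(days = 2, seed = 8,
                   sensors = data.frame(
                     sensor_id = c("S1", "S9"), bias = c(0, 1),
                     noise_sd = c(0.4, 0.4), transition_lag = c(0, 0)))
  a <- simulate_chamber(one)$series[["S1/T1"]]$values
  b <- simulate_chamber(two)$series[["S1/T1"]]$values
  expect_identical(a, b)
})

test_that("default four-trial plan matches the stated design", {
  plan <- default_trial_plan()
  expect_equal(vapply(plan, `[[`, numeric(1), "day_setpoint"),
               c(T1 = 30, T2 = 24, T3 = 28, T4 = 26))
  for (tr in plan) {
    expect_equal(tr$day_hours, 16.5)
    expect_equal(tr$night_hours, 7.5)
    expect_equal(as.numeric(tr$window[2] - tr$window[1], units = "days"), 35)
    expect_equal(as.numeric(tr$analysis_window[2] - tr$analysis_window[1],
                            units = "days"), 28)
  }
  expect_equal(length(minute_grid(plan$T1$analysis_window[1],
                                  plan$T1$analysis_window[2])), 40320L)
})

test_that("labels_to_truth reports per-kind recall and NA when nothing planted", {
  sim <- simulate_chamber(small_sim(days = 7, seed = 13, anomalies = list(
    anomaly_event("power_surge_spike", "2021-01-06T10:00:00", 1, 8))))
  s <- sim$series[["S1/T1"]]
  tb <- zscore_outliers(alt_decompose(coalesce(s, build_surrogate(s))))
  tt <- labels_to_truth(sim$labels, tb)
  expect_equal(tt$per_kind$recall[tt$per_kind$kind == "power_surge_spike"], 1)
  expect_lt(tt$false_flag_rate, 0.02)

  clean <- simulate_chamber(small_sim(days = 7, seed = 13))
  s2 <- clean$series[["S1/T1"]]
  tb2 <- zscore_outliers(alt_decompose(coalesce(s2, build_surrogate(s2))))
  tt2 <- labels_to_truth(clean$labels, tb2)
  expect_true(is.na(tt2$recall))
  expect_equal(nrow(tt2$per_kind), 0L)
})

test_that("planted severity-vs-operations relationships are recovered in sign", {
  # spikes whose log severity follows the example effect size, log|z| ~
  # 3.9 - 0.006 * A(t), against the cumulative operations of hour-long
  # daily visits: the stability GLM should recover the negative slope. The
  # intercept keeps every planted spike above the flagging threshold across
  # the whole A range, so truncation does not hide the planted trend.
  noise_sd <- 0.4
  base_cfg <- function(seed, anns = list()) {
    small_sim(days = 7, seed = seed, noise_sd = noise_sd, anomalies = anns,
              routine_visit_minutes = 60)
  }
  dry <- simulate_chamber(base_cfg(1))
  am0 <- cumulative_agr_ops(events_to_minutes(
    dry$events$T1, dry$config$trials$T1$window))
  spike_times <- as_naive_time(c(t(outer(
    sprintf("2021-01-%02d", 4:10), c("T11:00:00", "T15:00:00", "T20:00:00"),
    paste0))))
  a_at <- am0$cumulative[match(as.numeric(spike_times),
                               as.numeric(am0$timestamp))]
  anns <- lapply(seq_along(spike_times), function(k) {
    anomaly_event("power_surge_spike", spike_times[k], 1,
                  magnitude = noise_sd * exp(3.9 - 0.006 * a_at[k]))
  })
  wins <- 0L
  for (r in 1:20) {
    sim <- simulate_chamber(base_cfg(700 + r, anns))
    s <- sim$series[["S1/T1"]]
    tb <- zscore_outliers(alt_decompose(coalesce(s, build_surrogate(s))))
    am <- cumulative_agr_ops(events_to_minutes(
      sim$events$T1, sim$config$trials$T1$window))
    ri <- regression_input(tb, am)
    if (nrow(ri) >= 5 && length(unique(ri$agr_ops)) >= 2) {
      fit <- fit_stability_glm(ri)
      if (fit$estimate[fit$term == "agr_ops"] < 0) wins <- wins + 1L
    }
  }
  expect_gte(wins, 19L)
})
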