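# Surrogate profile construction, coalescing, and both decompositions.

test_that("surrogate slots are per-slot medians, robust to spikes", {
  s <- mk_series(rep(25, 3 * 1440))
  p <- build_surrogate(s)
  expect_equal(p$slots, rep(25, 1440))
  expect_equal(p$support, rep(3L, 1440))

  # slot 08:00 observed {24, 25, 100}: median shrugs off the spike
  vals <- rep(25, 3 * 1440)
  slot0800 <- 8 * 60 + 1
  vals[slot0800 + c(0, 1, 2) * 1440] <- c(24, 25, 100)
  p2 <- build_surrogate(mk_series(vals))
  expect_equal(p2$slots[slot0800], 25)

  # even-count median = mean of the two central order statistics
  vals4 <- rep(20, 4 * 1440)
  vals4[slot0800 + (0:3) * 1440] <- c(1, 2, 10, 20)
  p4 <- build_surrogate(mk_series(vals4))
  expect_equal(p4$slots[slot0800], 6)
})

test_that("surrogate equals the brute-force per-slot median oracle on noisy square waves", {
  set.seed(91)
  wave <- square_wave(28)
  s <- mk_series(wave + stats::rnorm(length(wave), 0, 0.2))
  p <- build_surrogate(s)
  expect_equal(p$slots, oracle_slot_medians(s))
  expect_lt(max(abs(p$slots - wave[1:1440])), 0.2)
})

test_that("zero-support slots are filled by circular interpolation; all-missing errors", {
  vals <- square_wave(3)
  slot <- rep(1:1440, 3)
  vals[slot %in% c(1, 2, 720)] <- NA  # kill slots at midnight wrap + noon
  p <- build_surrogate(mk_series(vals))
  expect_equal(sum(p$support == 0), 3L)
  expect_true(all(is.finite(p$slots)))
  # noon slot sits between equal day-setpoint neighbours
  expect_equal(p$slots[720], 30)
  # midnight slots interpolate across the wrap between night values
  expect_equal(p$slots[1:2], c(24, 24))

  expect_error(build_surrogate(mk_series(rep(NA_real_, 1440))),
               "no surrogate support")
  expect_error(build_surrogate(mk_series(rep(25, 100))), "full day")
})

test_that("surrogate building is idempotent on its own tiled profile", {
  set.seed(5)
  s <- mk_series(square_wave(10) + stats::rnorm(10 * 1440, 0, 0.3))
  p <- build_surrogate(s)
  tiled <- mk_series(rep(p$slots, 10))
  expect_equal(build_surrogate(tiled)$slots, p$slots)
})

test_that("coalesce fills exactly the missing minutes from the matching slot", {
  set.seed(17)
  vals <- square_wave(6) + stats::rnorm(6 * 1440, 0, 0.2)
  full <- mk_series(vals)
  p <- build_surrogate(full)

  co0 <- coalesce(full, p)
  expect_identical(co0$coalesced, vals)
  expect_false(any(co0$filled))

  miss <- sample(length(vals), round(0.3 * length(vals)))
  vals_na <- vals
  vals_na[miss] <- NA
  s <- mk_series(vals_na)
  co <- coalesce(s, build_surrogate(s))
  expect_false(anyNA(co$coalesced))
  expect_equal(which(co$filled), sort(miss))
  # pointwise lookup oracle for every filled minute
  sur <- build_surrogate(s)
  slot <- (as.integer(as.numeric(s$timestamps) / 60) %% 1440L) + 1L
  expect_identical(co$coalesced[miss], sur$slots[slot[miss]])
  # observed minutes unchanged
  expect_identical(co$coalesced[-sort(miss)], vals[-sort(miss)])

  # an all-missing series coalesces to the tiled surrogate
  s_empty <- mk_series(rep(NA_real_, 6 * 1440))
  co_all <- coalesce(s_empty, p)
  expect_identical(co_all$coalesced, rep(p$slots, 6))

  expect_error(coalesce(mk_series(vals, trial_id = "T9"), p),
               "surrogate was built for")
})

test_that("alternative decomposition satisfies its additive identity exactly", {
  set.seed(23)
  vals <- square_wave(6) + stats::rnorm(6 * 1440, 0, 0.2)
  vals[sample(6 * 1440, 500)] <- NA
  s <- mk_series(vals)
  p <- build_surrogate(s)
  d <- alt_decompose(coalesce(s, p))
  expect_identical(d$coalesced, d$seasonal + d$residuals)
  expect_true(all(d$residuals[d$filled] == 0))

  # tiled surrogate has residual identically zero
  d0 <- alt_decompose(coalesce(mk_series(rep(p$slots, 6)), p))
  expect_true(all(d0$residuals == 0))

  # a constant shift lands entirely in the residuals
  d1 <- alt_decompose(coalesce(mk_series(rep(p$slots, 6) + 1), p))
  expect_equal(d1$residuals, rep(1, 6 * 1440))
})

test_that("a one-minute spike shows up in the residual at its oracle value", {
  vals <- square_wave(5)
  k <- 2 * 1440 + 601  # 10:00 on day 3
  vals[k] <- vals[k] + 5
  s <- mk_series(vals)
  p <- build_surrogate(s)
  d <- alt_decompose(coalesce(s, p))
  # slot median across {30,30,35,30,30} stays 30, so the residual is the
  # spike minus the (unmoved) slot median
  expect_equal(d$residuals[k], 5)
  expect_equal(sum(d$residuals != 0), 1L)
})

test_that("standard additive decomposition matches stats::decompose to 1e-9", {
  # linear ramp + square wave, daily period on the minute grid
  n <- 4 * 1440
  x <- square_wave(4) + seq(0, 2, length.out = n)
  d <- standard_additive_decompose(coalesce(mk_series(x),
                                            build_surrogate(mk_series(x))))
  ref <- stats::decompose(stats::ts(x, frequency = 1440), type = "additive")
  expect_lt(max(abs(d$trend - as.numeric(ref$trend)), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(d$seasonal - as.numeric(ref$seasonal))), 1e-9)
  expect_lt(max(abs(d$residuals - as.numeric(ref$random)), na.rm = TRUE),
            1e-9)
  # identity wherever the trend is defined
  ok <- !is.na(d$trend)
  expect_lt(max(abs(d$coalesced - d$trend - d$seasonal - d$residuals)[ok]),
            1e-12)
  # seasonal figure has zero mean over one period
  expect_lt(abs(mean(d$seasonal[1:1440])), 1e-9)
  # edges undefined within half a period
  expect_true(all(is.na(d$trend[1:720])))
  expect_true(all(is.na(d$trend[(n - 719):n])))
})

test_that("standard decomposition handles pure-periodic and constant input", {
  x <- square_wave(4)
  d <- standard_additive_decompose(mk_series(x))
  expect_lt(max(abs(d$residuals), na.rm = TRUE), 1e-9)

  dc <- standard_additive_decompose(mk_series(rep(21.5, 4 * 1440)))
  expect_lt(max(abs(dc$seasonal)), 1e-9)
  expect_lt(max(abs(dc$trend - 21.5), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(dc$residuals), na.rm = TRUE), 1e-9)

  expect_error(standard_additive_decompose(mk_series(rep(1, 1500))),
               "2 periods")
  expect_error(standard_additive_decompose(mk_series(c(NA, rep(1, 2879)))),
               "missing")
})
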