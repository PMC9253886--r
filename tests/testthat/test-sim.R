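# Synthetic-recording generator: schedule statistics, determinism, band
# content, event insertion, truth bookkeeping.

test_that("schedule fractions follow the alternating-renewal expectation", {
  # two-state oracle: expected NREM fraction = dwell_N / (dwell_A + dwell_N)
  cfg <- sim_config(duration_s = 6 * 3600, states = c("AWAKE", "NREM"),
                    dwell_light = c(AWAKE = 300, NREM = 600, REM = 80),
                    dwell_dark = c(AWAKE = 300, NREM = 600, REM = 80),
                    seed = 1)
  fr <- mean(as.character(make_state_schedule(cfg)) == "NREM")
  expect_equal(fr, 600 / 900, tolerance = 0.10)
})

test_that("degenerate single-state config yields that state everywhere", {
  cfg <- sim_config(duration_s = 300, states = "AWAKE", seed = 2)
  expect_true(all(make_state_schedule(cfg) == "AWAKE"))
})

test_that("the schedule is deterministic under a fixed seed and REM only follows NREM", {
  cfg <- sim_config(duration_s = 4 * 3600, seed = 33)
  s1 <- make_state_schedule(cfg)
  s2 <- make_state_schedule(cfg)
  expect_identical(s1, s2)
  st <- as.character(s1)
  rem_starts <- which(st[-1] == "REM" & st[-length(st)] != "REM") + 1L
  expect_true(all(st[rem_starts - 1L] == "NREM"))
  expect_error(sim_config(duration_s = 100, states = "REM"), "REM requires NREM")
  expect_error(sim_config(duration_s = 100,
                          dwell_light = c(AWAKE = -5, NREM = 600, REM = 80)),
               "positive")
})

test_that("synthesis is bit-identical under a fixed seed", {
  cfg <- quiet_config(duration_s = 70, seed = 9)
  r1 <- synthesize(cfg)
  r2 <- synthesize(cfg)
  expect_identical(r1$channels, r2$channels)
  expect_identical(r1$activity, r2$activity)
})

test_that("recording dimensions and truth cover the configured duration", {
  cfg <- nrem_config(duration_s = 180, seed = 3)
  rec <- synthesize(cfg)
  expect_identical(nrow(rec$channels), 180L * 512L)
  expect_identical(ncol(rec$channels), 2L)
  expect_length(rec$truth$state, 180L)
  expect_length(rec$activity, 180L)
  ev <- rec$truth$events
  if (nrow(ev)) {
    expect_true(all(ev$onset_s >= 0 & ev$offset_s <= 180))
    expect_true(all(diff(ev$onset_s[ev$type == "spwr"]) > 0))
  }
})

test_that("band power scales monotonically with the configured amplitude", {
  sr <- 512
  rms_band <- function(amp) {
    ba <- matrix(c(0.02, 0.07, 0.02, amp, 0.015, 0.09, 0.04, 0.01, 0.05),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("delta", "theta", "gamma"),
                                 c("AWAKE", "NREM", "REM")))
    rec <- synthesize(quiet_config(duration_s = 70, seed = 4,
                                   band_amplitudes = ba))
    lfprhythms:::rms(bandpass(rec$channels[, 1], "theta", sr = sr))
  }
  powers <- vapply(c(0.02, 0.05, 0.1), rms_band, numeric(1))
  expect_true(all(diff(powers) > 0))
})

test_that("truth carrier frequencies follow counterphase 24 h sinusoids", {
  cfg <- quiet_config(duration_s = 90, seed = 100)
  sn <- synthesize_snippets(cfg, hours = seq(0, 46, by = 2), snippet_s = 60)
  th <- vapply(sn, function(r) mean(r$truth$f_theta), numeric(1))
  ga <- vapply(sn, function(r) mean(r$truth$f_gamma), numeric(1))
  hr <- seq(0, 46, by = 2)
  ft <- fit_circadian_sine(hr, th)
  fg <- fit_circadian_sine(hr, ga)
  expect_equal(ft$amplitude, 0.4, tolerance = 0.02)
  expect_equal(fg$amplitude, 8, tolerance = 0.4)
  expect_equal(abs(wrap_pi_test(ft$phase - fg$phase)), pi, tolerance = 0.05)
})

test_that("Poisson event counts follow rate x NREM duration", {
  cfg <- sim_config(duration_s = 1100, states = "NREM",
                    spwr = list(rate = 0.5, ripple_freq = 180, snr = 6,
                                duration_s = 0.05),
                    seed = 9)
  rec <- synthesize(cfg)
  n <- sum(rec$truth$events$type == "spwr")
  nrem_s <- sum(as.character(rec$truth$state) == "NREM")
  expect_gt(n, 0.5 * nrem_s - 3 * sqrt(0.5 * nrem_s))
  expect_lt(n, 0.5 * nrem_s + 3 * sqrt(0.5 * nrem_s))
})

test_that("band content above Nyquist is rejected at configuration time", {
  expect_error(sim_config(sample_rate = 256,
                          spwr = list(rate = 0.4, ripple_freq = 180, snr = 6,
                                      duration_s = 0.05)),
               "Nyquist")
})

test_that("activity is higher during AWAKE than during sleep states", {
  rec <- synthesize(sim_config(duration_s = 1800, seed = 8))
  st <- as.character(rec$truth$state)
  expect_gt(median(rec$activity[st == "AWAKE"]),
            5 * median(rec$activity[st != "AWAKE"]))
})
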