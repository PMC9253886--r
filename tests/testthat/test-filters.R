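# FIR tap rule, zero-phase bandpass, RMS envelopes, analytic signal.

test_that("tap-count rule reproduces the printed values at 2048 samples/s", {
  expect_identical(fir_num_taps(0.5, 4, 2048), 1329L)  # formula: 1329.87 -> 1329
  expect_identical(fir_num_taps(5, 12, 2048), 665L)    # 664 even -> 665
  expect_identical(fir_num_taps(30, 120, 2048), 401L)  # 51 -> 401 floor
  expect_error(fir_num_taps(12, 5, 2048), "band edges")
  expect_error(fir_num_taps(30, 1200, 2048), "band edges")
})

test_that("tap count is odd, floored at 401, non-increasing in bandwidth", {
  widths <- c(0.5, 1, 2, 5, 10, 30, 90)
  taps <- vapply(widths, function(w) fir_num_taps(20, 20 + w, 2048), integer(1))
  expect_true(all(taps %% 2L == 1L))
  expect_true(all(taps >= 401L))
  expect_true(all(diff(taps) <= 0))
})

test_that("bandpass passes in-band tones at zero lag and is linear", {
  sr <- 512
  t <- seq(0, 20 - 1 / sr, 1 / sr)
  x <- sin(2 * pi * 8 * t)
  y <- bandpass(x, "theta", sr = sr)
  # zero-phase contract: max cross-correlation at lag 0
  cc <- stats::ccf(x, y, lag.max = 20, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)
  expect_gt(stats::cor(x, y), 0.99)

  # linearity
  x2 <- sin(2 * pi * 7 * t)
  lhs <- bandpass(2 * x + 3 * x2, "theta", sr = sr)
  rhs <- 2 * bandpass(x, "theta", sr = sr) + 3 * bandpass(x2, "theta", sr = sr)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("stopband behaviour matches the designed frequency response", {
  # oracle: the designed filter's own transfer function magnitude
  sr <- 2048
  sp <- filter_spec(5, 12, sr)
  H <- function(f) Mod(sum(sp$h * exp(-2i * pi * f / sr * (seq_along(sp$h) - 1))))
  t <- seq(0, 20 - 1 / sr, 1 / sr)
  for (f in c(1, 2, 3)) {
    x <- sin(2 * pi * f * t)
    ratio <- lfprhythms:::rms(bandpass(x, sp)) / lfprhythms:::rms(x)
    expect_equal(ratio, H(f), tolerance = 0.02)
  }
  # deep stopband: a 40 Hz tone is attenuated below 1%
  expect_lt(lfprhythms:::rms(bandpass(sin(2 * pi * 40 * t), sp)) / lfprhythms:::rms(sin(2 * pi * 40 * t)),
            0.01)
})

test_that("filtering twice matches the designed-response prediction", {
  # oracle: for white noise, E||H^2 x - H x||^2 / E||H x||^2 equals
  # integral of H^2 (1 - H)^2 over integral of H^2 -- the transition-band
  # residual of the designed frequency response
  sr <- 512
  sp <- filter_spec(5, 12, sr)
  nfft <- 8192
  H <- Mod(stats::fft(c(sp$h, numeric(nfft - sp$n_taps))))
  expected <- sqrt(sum(H^2 * (1 - H)^2) / sum(H^2))
  set.seed(2)
  x <- rnorm(40 * sr)
  y1 <- bandpass(x, sp)
  y2 <- bandpass(y1, sp)
  observed <- lfprhythms:::rms(y2 - y1) / lfprhythms:::rms(y1)
  expect_lt(abs(observed - expected), 0.02)
  expect_gt(stats::cor(y1, y2), 0.97)
})

test_that("bandpass rejects series shorter than the filter", {
  expect_error(bandpass(rnorm(300), "theta", sr = 512), "longer than")
})

test_that("RMS envelope matches closed forms", {
  sr <- 512
  e <- rms_envelope(rep(-3, 20 * sr), sr)
  expect_equal(unique(e$values), 3)
  # sinusoid amplitude A, window >> period -> A/sqrt(2)
  t <- seq(0, 40 - 1 / sr, 1 / sr)
  e2 <- rms_envelope(2 * sin(2 * pi * 5 * t), sr, window_s = 8, step_s = 1)
  mid <- e2$values[e2$t > 4 & e2$t < 36]
  expect_equal(mid, rep(2 / sqrt(2), length(mid)), tolerance = 0.01)
  # step between a zero block and a sinusoid block
  x <- c(numeric(10 * sr), sin(2 * pi * 5 * t[1:(10 * sr)]))
  e3 <- rms_envelope(x, sr, window_s = 8, step_s = 1)
  expect_lt(max(e3$values[e3$t < 5]), 0.05)
  expect_equal(mean(e3$values[e3$t > 15]), 1 / sqrt(2), tolerance = 0.02)
  expect_error(rms_envelope(x, sr, step_s = 0), "step_s")
  expect_error(rms_envelope(rnorm(sr), sr, window_s = 8), "duration")
})

test_that("analytic signal phase/amplitude conventions hold", {
  sr <- 256
  t <- seq(0, 30 - 1 / sr, 1 / sr)
  a <- analytic_signal(1.7 * cos(2 * pi * 3 * t))
  expect_equal(a$phase[1], 0, tolerance = 1e-6)     # phase 0 at the peak
  interior <- 1000:6000
  expect_equal(mean(a$amplitude[interior]), 1.7, tolerance = 0.01)
  # phase wraps near +/-pi at troughs
  trough <- which.min(cos(2 * pi * 3 * t[1:sr]))
  expect_gt(abs(a$phase[trough]), pi - 0.05)
  # chirp instantaneous frequency from the unwrapped phase derivative
  f0 <- 2; f1 <- 4
  finst <- f0 + (f1 - f0) * t / max(t)
  chirp <- cos(2 * pi * cumsum(finst) / sr)
  ach <- analytic_signal(chirp)
  est <- diff(unwrap_phase(ach$phase)) * sr / (2 * pi)
  mid <- interior
  expect_lt(max(abs(est[mid] - finst[mid]) / finst[mid]), 0.05)
  # degenerate all-zero input is flagged
  z <- analytic_signal(numeric(100))
  expect_true(z$degenerate)
  expect_equal(z$amplitude, numeric(100))
})
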