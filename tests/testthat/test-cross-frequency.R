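# Modulation index, FAC/PAC matrices, averaging and maxima.

test_that("modulation index spans its closed-form extremes", {
  set.seed(31)
  ph <- runif(6000, -pi, pi)
  # phase-independent amplitude: MI near 0 and below surrogate bounds
  amp <- rexp(6000)
  expect_lt(as.numeric(modulation_index(ph, amp)), 0.005)
  st <- mi_surrogate_test(ph, amp)
  expect_false(st$significant)
  # all mass in one bin: MI = 1 under the log(n) normalisation
  bin <- ceiling((ph + pi) / (2 * pi) * 18)
  expect_equal(as.numeric(modulation_index(ph, as.numeric(bin == 7))), 1)
  # invariance to amplitude scaling and joint phase rotation
  amp2 <- (1 + 0.5 * cos(ph)) * rexp(6000)
  m0 <- as.numeric(modulation_index(ph, amp2))
  expect_equal(as.numeric(modulation_index(ph, 10 * amp2)), m0)
  rot <- wrap_pi(ph + 2 * pi / 18 * 3)   # whole-bin rotation
  expect_equal(as.numeric(modulation_index(rot, amp2)), m0, tolerance = 1e-12)
  expect_true(as.numeric(modulation_index(ph, amp2)) >= 0 && m0 <= 1)
})

test_that("MI grows monotonically with the configured coupling depth", {
  sr <- 512
  mi_at_depth <- function(depth) {
    cfg <- quiet_config(duration_s = 60, seed = 32,
                        pac = list(preferred_phase = 0,
                                   coupling_depth = depth))
    rec <- synthesize(cfg)
    th <- analytic_signal(bandpass(rec$channels[, 1], "theta", sr = sr))$phase
    ga <- analytic_signal(bandpass(rec$channels[, 1], "gamma", sr = sr))$amplitude
    as.numeric(modulation_index(th, ga))
  }
  mis <- vapply(c(0, 0.2, 0.5), mi_at_depth, numeric(1))
  expect_true(all(diff(mis) > 0))
})

test_that("both PAC methods recover the configured preferred phase", {
  sr <- 512
  for (phase in c(0, pi / 2)) {
    rec <- synthesize(quiet_config(duration_s = 120, seed = 33,
                                   pac = list(preferred_phase = phase,
                                              coupling_depth = 0.6)))
    ep <- epochs_from(rec, n = 12)
    m1 <- pac_matrix_cycles(ep, sr)
    m2 <- pac_matrix_hilbert(ep, sr)
    p1 <- preferred_phase(m1); p2 <- preferred_phase(m2)
    expect_lt(abs(wrap_pi_test(p1 - phase)), pi / 9)
    expect_lt(abs(wrap_pi_test(p2 - phase)), pi / 9)
    expect_lt(abs(wrap_pi_test(p1 - p2)), 2 * pi / 18)  # methods agree, one bin
    # the gamma row of maximum coupling sits at the configured carrier
    expect_equal(max_coupling_coordinates(m1)$row_value, 85, tolerance = 10)
  }
})

test_that("constant gamma amplitude gives a flat phase profile (cycles method)", {
  sr <- 512
  rec <- synthesize(quiet_config(duration_s = 100, seed = 34,
                                 pac = list(preferred_phase = 0,
                                            coupling_depth = 0)))
  m <- pac_matrix_cycles(epochs_from(rec, 12), sr)
  prof <- colMeans(m$values)
  expect_lt((max(prof) - min(prof)) / mean(prof), 0.25)
})

test_that("FAC matrix peaks at the driving theta-gamma frequency pair", {
  sr <- 512
  rec <- synthesize(quiet_config(
    duration_s = 100, seed = 35,
    circadian = list(theta_mean = 8, theta_amp = 0, gamma_mean = 70,
                     gamma_amp = 0, period_h = 24, phase_offset = 0),
    pac = list(preferred_phase = 0, coupling_depth = 0.8)))
  fm <- fac_matrix(epochs_from(rec, 10), sr)
  mx <- max_coupling_coordinates(fm)
  expect_equal(mx$col_value, 8.5, tolerance = 1)    # theta bin near 8 Hz
  expect_equal(mx$row_value, 75, tolerance = 10)    # gamma bin near 70 Hz
  expect_error(fac_matrix(epochs_from(rec, 5), sr), "insufficient")
})

test_that("averaging, Z-scoring and smoothing preserve structure", {
  set.seed(36)
  base <- matrix(rexp(9 * 18), 9, 18)
  mats <- lapply(1:10, function(i) {
    coupling_matrix(base, gamma_bins()$center,
                    lfprhythms:::phase_bin_centers(), "PAC-cycles", 1)
  })
  out <- average_zscore_smooth(mats)
  expect_equal(out$average$values, base)
  expect_equal(mean(out$zscored$values), 0, tolerance = 1e-12)
  expect_equal(sd(out$zscored$values), 1, tolerance = 1e-12)
  expect_identical(dim(out$smoothed), c(9L * 4L, 18L * 4L))
  # the upsampled argmax stays within one original bin of the raw argmax
  raw <- which(base == max(base), arr.ind = TRUE)
  sm <- which(out$smoothed == max(out$smoothed), arr.ind = TRUE)
  expect_lt(abs(sm[1] / 4 - raw[1]), 1.5)
  expect_lt(abs(sm[2] / 4 - raw[2]), 1.5)
  expect_error(average_zscore_smooth(mats[1:3]), "at least")
})

test_that("maximum coordinates resolve ties deterministically", {
  m <- coupling_matrix(matrix(1, 3, 4), c(35, 45, 55), c(-1, 0, 1, 2),
                       "PAC-cycles", 1)
  mx <- max_coupling_coordinates(m)
  expect_true(mx$tied)
  expect_identical(mx$row_index, 1L)
  expect_identical(mx$col_index, 1L)
  m$values[2, 3] <- 5
  mx2 <- max_coupling_coordinates(m)
  expect_identical(c(mx2$row_value, mx2$col_value), c(45, 1))
  expect_false(mx2$tied)
})

test_that("the gamma binning schemes match their declared shapes", {
  g9 <- gamma_bins("nonoverlap9")
  expect_identical(nrow(g9), 9L)
  expect_equal(range(c(g9$low, g9$high)), c(30, 120))
  g14 <- gamma_bins("overlap14")
  expect_identical(nrow(g14), 14L)
  expect_true(all(g14$high - g14$low == 10))
  expect_equal(range(c(g14$low, g14$high)), c(30, 120))
})
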