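# Vigilance staging: mixture fits, probability bands, binary smoothing,
# REM/AWAKE split, activity reclassification, hourly fractions.

test_that("two-Gaussian fit recovers mixture parameters", {
  set.seed(11)
  v <- c(rnorm(5e4, 1, 0.1), rnorm(5e4, 3, 0.3))
  fit <- fit_two_gaussians(v)
  expect_false(fit$failed)
  expect_equal(fit$low$mean, 1, tolerance = 0.05)
  expect_equal(fit$high$mean, 3, tolerance = 0.05)
  # 90/10 mixture: recovered component masses within 0.05
  v2 <- c(rnorm(9e4, 1, 0.1), rnorm(1e4, 3, 0.3))
  f2 <- fit_two_gaussians(v2)
  mass <- function(comp) comp$weight * comp$sd
  w_low <- mass(f2$low) / (mass(f2$low) + mass(f2$high))
  expect_equal(w_low, 0.9, tolerance = 0.05)
})

test_that("an effectively single-mode sample raises the failure flag", {
  set.seed(12)
  fit <- fit_two_gaussians(rnorm(2e4, 2, 0.5))
  expect_true(fit$failed)
  expect_error(theta_delta_threshold(fit), "did not separate")
})

test_that("NREM probability takes the printed stepped values", {
  low <- list(mean = 2, sd = 0.5)
  expect_identical(nrem_probability(2 + 0.5 * 0.5, low), 1)
  expect_identical(nrem_probability(2 + 1.5 * 0.5, low), 0.397)
  expect_identical(nrem_probability(2 + 2.5 * 0.5, low), 0.067)
  expect_identical(nrem_probability(2 + 3.5 * 0.5, low), 0)
  # non-increasing step function of the ratio
  g <- seq(0, 6, by = 0.01)
  p <- nrem_probability(g, low)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p %in% c(1, 0.397, 0.067, 0)))
})

test_that("binary NREM follows the 8 s flank-averaging rule", {
  expect_identical(binary_nrem(rep(1, 30)), rep(1L, 30))
  # isolated single 1 amid 0.067s: both flanks average below 0.5
  p <- rep(0.067, 30); p[15] <- 1
  expect_identical(binary_nrem(p)[15], 0L)
  # 20 s run of 1s: interior all 1, direct evaluation at the boundary
  p2 <- c(rep(0, 20), rep(1, 20), rep(0, 20))
  b <- binary_nrem(p2)
  expect_true(all(b[25:36] == 1L))
  oracle <- vapply(seq_along(p2), function(i) {
    lo <- max(i - 8, 1); before <- if (i > 1) mean(p2[lo:(i - 1)]) else 0
    hi <- min(i + 8, length(p2))
    after <- if (i < length(p2)) mean(p2[(i + 1):hi]) else 0
    as.integer(before >= 0.5 || after >= 0.5)
  }, integer(1))
  expect_identical(b, oracle)
})

test_that("the Gaussian-intersection threshold solves the density equality", {
  sym <- structure(list(low = list(mean = 1, sd = 0.2, weight = 5),
                        high = list(mean = 2, sd = 0.2, weight = 5),
                        failed = FALSE), class = "gaussian_pair")
  expect_equal(theta_delta_threshold(sym)$threshold, 1.5, tolerance = 1e-9)
  # closed-form quadratic oracle for unequal SDs
  pair <- structure(list(low = list(mean = 1, sd = 0.1, weight = 7),
                         high = list(mean = 2, sd = 0.4, weight = 7),
                         failed = FALSE), class = "gaussian_pair")
  thr <- theta_delta_threshold(pair)
  dens <- function(x, c) c$weight * exp(-(x - c$mean)^2 / (2 * c$sd^2))
  expect_equal(dens(thr$threshold, pair$low), dens(thr$threshold, pair$high),
               tolerance = 1e-8)
  expect_false(thr$flagged)
})

test_that("REM requires a supra-threshold ratio and NREM flanking", {
  nrem <- c(rep(1L, 10), rep(0L, 10), rep(1L, 5), rep(0L, 10))
  td <- rep(1, 35)
  td[12] <- 5            # high ratio inside an NREM-flanked run -> REM
  td[30] <- 5            # run [26..35] touches NREM run on its left -> REM
  st <- classify_rem_awake(td, nrem, threshold = 3)
  expect_identical(as.character(st)[12], "REM")
  expect_identical(as.character(st)[30], "REM")
  # ratio exactly at the threshold stays AWAKE (strict inequality)
  td[13] <- 3
  st2 <- classify_rem_awake(td, nrem, threshold = 3)
  expect_identical(as.character(st2)[13], "AWAKE")
  # high ratio with AWAKE on both sides (no NREM anywhere) -> AWAKE
  st3 <- classify_rem_awake(td, rep(0L, 35), threshold = 3)
  expect_false(any(st3 == "REM"))
})

test_that("activity reclassification applies its three passes in order", {
  st <- c(rep("NREM", 10), rep("REM", 5), rep("AWAKE", 10))
  act <- c(rep(1, 10), rep(30, 5), rep(20, 10))
  # pass 1: REM with activity above the pooled REM/AWAKE median (20) -> AWAKE
  out <- reclassify_by_activity(st, act)
  expect_false(any(out$state[11:15] == "REM"))
  # pass 2: AWAKE below the NREM activity median -> REM (pass 3 then checks
  # what precedes the new run beyond the transition gap)
  act2 <- c(rep(5, 10), rep(1, 5), rep(20, 9), 0.5)
  out2 <- reclassify_by_activity(st, act2)
  expect_identical(as.character(out2$state)[15], "REM")
  # all-zero activity: strict inequalities make passes 1-2 no-ops
  out3 <- reclassify_by_activity(st, rep(0, 25))
  expect_identical(as.character(out3$state)[1:15], st[1:15])
  # no NREM: pass 2 skipped with a flag
  out4 <- reclassify_by_activity(rep("AWAKE", 20), rep(0, 20))
  expect_match(out4$flags, "no NREM", all = FALSE)
})

test_that("REM runs reached through a short transition gap survive pass 3", {
  st <- c(rep("NREM", 10), "AWAKE", "AWAKE", rep("REM", 6), rep("AWAKE", 7))
  out <- reclassify_by_activity(st, rep(0, 25))
  expect_identical(as.character(out$state)[13:18], rep("REM", 6))
  # a REM run deep inside AWAKE is reverted
  st2 <- c(rep("NREM", 5), rep("AWAKE", 10), rep("REM", 4), rep("AWAKE", 6))
  out2 <- reclassify_by_activity(st2, rep(0, 25))
  expect_false(any(out2$state == "REM"))
})

test_that("hourly fractions sum to 100 and match a counting oracle", {
  st <- rep(c("AWAKE", "NREM"), c(1800, 1800))
  hf <- hourly_fractions(rep(st, 2))
  expect_equal(hf$AWAKE + hf$NREM + hf$REM, rep(100, 2))
  expect_equal(hf$NREM, rep(50, 2))
  hf2 <- hourly_fractions(rep("NREM", 3600))
  expect_equal(unlist(hf2[1, c("AWAKE", "NREM", "REM")], use.names = FALSE),
               c(0, 100, 0))
  expect_true(attr(hourly_fractions(rep("NREM", 4000)), "partial_last_hour"))
})

test_that("light-phase NREM beats dark-phase NREM on default schedules", {
  cfg <- sim_config(duration_s = 3600, seed = 51)
  # truth property on a 24 h schedule
  cfg24 <- sim_config(duration_s = 24 * 3600, seed = 52)
  st <- as.character(make_state_schedule(cfg24))
  light <- is_light(seq_along(st) - 1, cfg24)
  expect_gt(mean(st[light] == "NREM"), mean(st[!light] == "NREM"))
  expect_gt(mean(st[!light] == "AWAKE"), mean(st[light] == "AWAKE"))
})
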