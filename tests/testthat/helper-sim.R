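# Shared fixtures and matching utilities for the test suite.
# All fixtures are generated in code at test time; nothing is stored.

# Quiet config: no events, optional single state -- for oscillation-level
# checks where transients would be confounders.
quiet_config <- function(duration_s = 120, states = "AWAKE", seed = 5, ...) {
  sim_config(duration_s = duration_s, states = states, seed = seed,
             spwr = list(rate = 0, ripple_freq = 180, snr = 6,
                         duration_s = 0.05),
             spindle = list(rate = 0, freq = 15, snr = 8, duration_s = 0.3,
                            coupled_fraction = 0, latency_mean = 2.2,
                            latency_sd = 1.5),
             ...)
}

# NREM-heavy two-state config for event/synchrony work.
nrem_config <- function(duration_s = 600, seed = 21, ...) {
  sim_config(duration_s = duration_s, states = c("AWAKE", "NREM"),
             dwell_light = c(AWAKE = 60, NREM = 300, REM = 80),
             seed = seed, ...)
}

# consecutive non-overlapping 8 s epochs from channel 1
epochs_from <- function(rec, n = 14, window_s = 8) {
  sr <- rec$sample_rate
  starts <- seq(0, by = window_s, length.out = n)
  lapply(starts, function(s0) {
    rec$channels[(s0 * sr + 1):((s0 + window_s) * sr), 1]
  })
}

# one-to-one onset matching with tolerance; returns c(recall, precision)
match_onsets <- function(det_on, true_on, tol_s) {
  used <- rep(FALSE, length(det_on))
  hit <- 0L
  for (tt in true_on) {
    j <- which(!used & abs(det_on - tt) <= tol_s)
    if (length(j)) { used[j[1L]] <- TRUE; hit <- hit + 1L }
  }
  c(recall = hit / length(true_on),
    precision = if (length(det_on)) sum(used) / length(det_on) else NA_real_)
}

# interval-overlap recall/precision between detected and truth event tables
match_overlap <- function(det, truth) {
  rec <- vapply(seq_len(nrow(truth)), function(i) {
    any(det$onset_s < truth$offset_s[i] & det$offset_s > truth$onset_s[i])
  }, logical(1))
  prec <- vapply(seq_len(nrow(det)), function(i) {
    any(truth$onset_s < det$offset_s[i] & truth$offset_s > det$onset_s[i])
  }, logical(1))
  c(recall = mean(rec), precision = mean(prec))
}

wrap_pi_test <- function(x) atan2(sin(x), cos(x))

# Spindle-band fixture carrying a supra-threshold excursion shorter than the
# 5 ms duration floor. A two-sample impulse is band-limited by the spindle
# filter; its amplitude is searched upward until the floorless detector sees
# an event at the insertion point whose duration is below 5 ms. Returns NULL
# when no such scale exists for this noise realisation.
make_subfloor_blip <- function(seed = 807, sr = 512, dur_s = 60) {
  imp <- numeric(dur_s * sr)
  mid <- dur_s / 2
  imp[mid * sr + (0:1)] <- 1
  ir <- bandpass(imp, "spindle", sr = sr)
  for (s in seed + 0:9) {   # some noise realisations admit no such scale
    set.seed(s)
    base <- pink_noise(dur_s * sr, sr, 1, 0.01)
    env0 <- abs(bandpass(base, "spindle", sr = sr))
    thr0 <- mean(env0) + 5 * sd(env0)
    for (scale in seq(0.6, 1.3, by = 0.005)) {
      x <- base + ir * (scale * thr0 / max(abs(ir)))
      t0 <- detect_spindles(x, sr, rep("NREM", dur_s), smooth_s = 0.002,
                            min_gap_s = 0.002, min_duration_ms = 0)
      hit <- t0$events$onset_s > mid - 0.5 & t0$events$onset_s < mid + 0.5
      if (any(hit) && all(t0$events$duration_ms[hit] < 5)) {
        return(list(x = x, mid = mid))
      }
    }
  }
  NULL
}

# von Mises sampler (Best & Fisher rejection algorithm)
rvonmises <- function(n, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0L
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- sign(u[3] - 0.5) * acos(f)
    }
  }
  out
}

# kappa with E[resultant length] = A(kappa) = I1(kappa)/I0(kappa) = target
vm_kappa_for_ispc <- function(target) {
  uniroot(function(k) besselI(k, 1) / besselI(k, 0) - target, c(0.05, 50))$root
}
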