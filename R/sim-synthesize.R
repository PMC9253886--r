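# Synthetic two-channel LFP synthesis with per-second ground truth.
#
# Channel 1 emulates a ventral-CA1 electrode (delta + theta + gamma +
# sharp-wave-ripples + 1/f^alpha background), channel 2 a medial-prefrontal
# electrode (phase-lagged delta + attenuated shared theta/gamma + spindles +
# independent background). Every stochastic element is driven by the config
# seed, so a fixed seed yields bit-identical output.

#' 1/f^alpha ("pink") background noise
#'
#' Spectral shaping of white Gaussian noise: Fourier magnitudes are scaled by
#' f^(-alpha/2); frequencies below 0.1 Hz are clamped to the 0.1 Hz gain so
#' the trace does not wander. The result is rescaled to the requested RMS.
#'
#' @param n number of samples.
#' @param sr sampling rate, samples/s.
#' @param alpha spectral exponent (power ~ 1/f^alpha).
#' @param rms_target output RMS (mV).
#' @return numeric vector of length n.
#' @export
pink_noise <- function(n, sr, alpha = 1, rms_target = 1) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w * rms_target / rms(w))
  W <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * sr / n
  f <- pmin(f, sr - f)            # two-sided frequency axis
  g <- pmax(f, 0.1)^(-alpha / 2)
  g[1L] <- 0                      # no DC
  x <- Re(stats::fft(W * g, inverse = TRUE)) / n
  x * rms_target / rms(x)
}

# Hann window of length n (periodic-agnostic symmetric form).
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# Sharp-wave-ripple template: Hann-windowed ripple-frequency sinusoid riding
# on a low-frequency deflection whose mean over the event is zero, so the
# event mean stays within the flanking-baseline SD criterion.
spwr_template <- function(sr, dur_s, ripple_freq, amp) {
  n <- max(8L, round(dur_s * sr))
  tau <- seq(0, n - 1) / sr
  h <- hann_window(n)
  ripple <- amp * h * sin(2 * pi * ripple_freq * tau)
  sw <- -0.6 * amp * (h - mean(h))
  ripple + sw
}

spindle_template <- function(sr, dur_s, freq, amp) {
  n <- max(8L, round(dur_s * sr))
  tau <- seq(0, n - 1) / sr
  amp * hann_window(n) * sin(2 * pi * freq * tau)
}

# Draw event onset times (s) uniformly over NREM runs, leaving room for the
# template; expected count = rate * total NREM seconds (Poisson), followed by
# a short dead time so truth events never overlap (overlapping templates are
# not individually recoverable by any detector).
draw_event_onsets <- function(runs_s, rate, dur_s, margin = 0.1,
                              min_sep_s = 0.15) {
  if (nrow(runs_s) == 0L || rate <= 0) return(numeric(0))
  lo <- runs_s$start - 1 + margin
  hi <- runs_s$end - dur_s - margin
  len <- pmax(hi - lo, 0)
  total_nrem <- sum(runs_s$end - runs_s$start + 1)
  avail <- sum(len)
  if (avail <= 0) return(numeric(0))
  k <- stats::rpois(1L, rate * total_nrem)
  if (k == 0L) return(numeric(0))
  u <- stats::runif(k, 0, avail)
  cum <- cumsum(len)
  run_idx <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
  on <- sort(lo[run_idx] + (u - c(0, cum)[run_idx]))
  sep <- max(min_sep_s, dur_s + 0.02)
  keep <- c(TRUE, diff(on) >= sep)
  while (!all(keep)) {           # sequential dead-time thinning
    on <- on[keep]
    keep <- c(TRUE, diff(on) >= sep)
  }
  on
}

#' Synthesize a ground-truth-labelled two-channel LFP recording
#'
#' Generates the vigilance schedule, oscillation carriers (theta and gamma
#' with counterphase circadian frequency modulation, delta with a smooth
#' frequency drift), theta-phase-modulated gamma amplitude, a phase-lagged
#' and jittered channel-2 delta, NREM sharp-wave-ripples (channel 1) and
#' spindles (channel 2, partly coupled to ripples), 1/f^alpha background and
#' a state-correlated per-second activity trace.
#'
#' @param config a [sim_config()].
#' @return object of class "synthetic_recording": list with \code{channels}
#'   (n x 2 matrix, mV), \code{sample_rate}, \code{duration_s},
#'   \code{start_clock_h}, \code{activity} (per-second), and \code{truth}
#'   (per-second state, instantaneous theta/gamma peak frequencies, event
#'   table with onset/offset/type, PAC preferred phase, delta phase lag).
#' @export
synthesize <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, synthesize_impl(config))
}

synthesize_impl <- function(config) {
  sr <- config$sample_rate
  n_s <- as.integer(ceiling(config$duration_s))
  n <- n_s * sr
  t <- seq(0, n - 1) / sr
  sec_centers <- seq_len(n_s) - 0.5

  states <- make_state_schedule_impl(config)
  st_idx <- as.integer(states)              # 1 AWAKE, 2 NREM, 3 REM

  # per-sample band amplitudes, linearly interpolated between second centers
  amp_of <- function(band) {
    per_sec <- config$band_amplitudes[band, c("AWAKE", "NREM", "REM")][st_idx]
    stats::approx(sec_centers, per_sec, xout = t, rule = 2)$y
  }
  a_delta <- amp_of("delta"); a_theta <- amp_of("theta"); a_gamma <- amp_of("gamma")

  # circadian carrier frequencies (clock-time referenced)
  cc <- config$circadian
  h <- config$start_clock_h + t / 3600
  f_theta <- cc$theta_mean + cc$theta_amp *
    sin(2 * pi * h / cc$period_h + cc$phase_offset)
  g_off <- cc$phase_offset + if (isTRUE(config$counterphase)) pi else 0
  f_gamma <- cc$gamma_mean + cc$gamma_amp * sin(2 * pi * h / cc$period_h + g_off)

  ph_theta <- 2 * pi * cumsum(f_theta) / sr
  ph_gamma <- 2 * pi * cumsum(f_gamma) / sr
  theta <- a_theta * cos(ph_theta)
  d <- config$pac$coupling_depth
  env <- (1 + d * cos(ph_theta - config$pac$preferred_phase)) / (1 + d)
  gamma <- a_gamma * env * cos(ph_gamma)

  # delta oscillator with smooth per-second frequency drift
  f_del_s <- config$delta_freq +
    moving_average(stats::rnorm(n_s, 0, config$delta_freq_sd), 5L)
  f_del_s <- pmin(pmax(f_del_s, 0.6), 3.8)
  f_delta <- stats::approx(sec_centers, f_del_s, xout = t, rule = 2)$y
  ph_delta <- 2 * pi * cumsum(f_delta) / sr
  delta1 <- a_delta * cos(ph_delta)

  jsd <- config$delta_sync$phase_jitter_sd
  if (jsd > 0) {
    j_s <- moving_average(stats::rnorm(n_s), 3L)
    j_s <- j_s * jsd / stats::sd(j_s)
    jit <- stats::approx(sec_centers, j_s, xout = t, rule = 2)$y
  } else {
    jit <- numeric(n)
  }
  delta2 <- a_delta * cos(ph_delta - config$delta_sync$phase_lag - jit)

  pink1 <- pink_noise(n, sr, config$pink_alpha, config$noise_rms)
  pink2 <- pink_noise(n, sr, config$pink_alpha, config$noise_rms)

  ch1 <- delta1 + theta + gamma + pink1
  ch2 <- delta2 + config$ch2_gain * (theta + gamma) + pink2

  # ---- transient events -------------------------------------------------
  nrem_runs <- logical_runs(st_idx == 2L)
  events <- list()

  probe_n <- min(n, 60L * sr)
  rip_on <- numeric(0)
  if (config$spwr$rate > 0 && nrow(nrem_runs) > 0) {
    rip_edges <- band_edges("ripple")
    rip_spec <- filter_spec(rip_edges[1], min(rip_edges[2], sr / 2 - 1), sr)
    sigma_rip <- rms(bandpass(pink1[seq_len(probe_n)], rip_spec))
    rip_on <- draw_event_onsets(nrem_runs, config$spwr$rate,
                                config$spwr$duration_s)
    if (length(rip_on) > 0) {
      tmpl <- spwr_template(sr, config$spwr$duration_s,
                            config$spwr$ripple_freq,
                            config$spwr$snr * sigma_rip)
      for (on in rip_on) {
        i0 <- round(on * sr) + 1L
        idx <- i0:(i0 + length(tmpl) - 1L)
        ch1[idx] <- ch1[idx] + tmpl
      }
      events$spwr <- data.frame(type = "spwr", onset_s = rip_on,
                                offset_s = rip_on + config$spwr$duration_s)
    }
  }

  if ((config$spindle$rate > 0 || config$spindle$coupled_fraction > 0) &&
      nrow(nrem_runs) > 0) {
    spn_edges <- band_edges("spindle")
    spn_spec <- filter_spec(spn_edges[1], spn_edges[2], sr)
    sigma_spn <- rms(bandpass(pink2[seq_len(probe_n)], spn_spec))
    sp <- config$spindle
    sp_on <- draw_event_onsets(nrem_runs, sp$rate, sp$duration_s,
                               min_sep_s = sp$duration_s + 0.2)
    if (length(rip_on) > 0 && sp$coupled_fraction > 0) {
      coupled <- rip_on[stats::runif(length(rip_on)) < sp$coupled_fraction]
      if (length(coupled) > 0) {
        lat <- pmax(stats::rnorm(length(coupled), sp$latency_mean,
                                 sp$latency_sd), 0.05)
        cand <- coupled + lat
        keep <- in_nrem_run(cand, sp$duration_s, nrem_runs)
        sp_on <- c(sp_on, cand[keep])
      }
    }
    sp_on <- sort(sp_on[sp_on + sp$duration_s < config$duration_s])
    if (length(sp_on) > 1L) {   # dead time across coupled + independent
      keep <- c(TRUE, diff(sp_on) >= sp$duration_s + 0.2)
      while (!all(keep)) {
        sp_on <- sp_on[keep]
        keep <- c(TRUE, diff(sp_on) >= sp$duration_s + 0.2)
      }
    }
    if (length(sp_on) > 0) {
      tmpl <- spindle_template(sr, sp$duration_s, sp$freq, sp$snr * sigma_spn)
      for (on in sp_on) {
        i0 <- round(on * sr) + 1L
        idx <- i0:(i0 + length(tmpl) - 1L)
        ch2[idx] <- ch2[idx] + tmpl
      }
      events$spindle <- data.frame(type = "spindle", onset_s = sp_on,
                                   offset_s = sp_on + sp$duration_s)
    }
  }
  events <- if (length(events)) do.call(rbind, c(events, make.row.names = FALSE))
            else data.frame(type = character(0), onset_s = numeric(0),
                            offset_s = numeric(0))

  act <- config$activity
  activity <- ifelse(st_idx == 1L,
                     stats::rlnorm(n_s, act$awake_meanlog, act$sdlog),
                     stats::rlnorm(n_s, act$rest_meanlog, act$sdlog))

  sec_i <- pmin(floor(sec_centers) * sr + sr %/% 2L + 1L, n)
  truth <- list(state = states,
                f_theta = f_theta[sec_i],
                f_gamma = f_gamma[sec_i],
                events = events,
                pac_preferred_phase = config$pac$preferred_phase,
                delta_phase_lag = config$delta_sync$phase_lag)

  structure(list(channels = cbind(vCA1 = ch1, mPFC = ch2),
                 sample_rate = sr, duration_s = n_s,
                 start_clock_h = config$start_clock_h,
                 lights_on_h = config$lights_on_h,
                 lights_off_h = config$lights_off_h,
                 activity = activity, truth = truth, config = config),
            class = "synthetic_recording")
}

# TRUE where [on, on + dur] lies inside some NREM run (runs in 1-based s).
in_nrem_run <- function(on, dur, runs_s) {
  if (length(on) == 0L) return(logical(0))
  ok <- logical(length(on))
  for (r in seq_len(nrow(runs_s))) {
    ok <- ok | (on >= runs_s$start[r] - 1 & on + dur <= runs_s$end[r])
  }
  ok
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(paste0("synthetic LFP recording: 2 channels, %d s @ %g ",
                     "samples/s, %d events, start %02d:00\n"),
              x$duration_s, x$sample_rate, nrow(x$truth$events),
              x$start_clock_h %% 24))
  print(round(100 * table(x$truth$state) / length(x$truth$state), 1))
  invisible(x)
}

#' Synthesize short snippets spread over a circadian sweep
#'
#' Rather than one multi-day continuous recording, generates a list of short
#' recordings whose clock start times step through the requested hours, so
#' circadian analyses (hourly spectral peaks, sine fits) can be run at a
#' fraction of the sample count. Each snippet gets a distinct derived seed.
#'
#' @param config a [sim_config()]; its duration is overridden per snippet.
#' @param hours numeric vector of start offsets in hours from the config's
#'   start clock time (e.g. \code{0:47} for a 48 h sweep).
#' @param snippet_s snippet duration in seconds.
#' @return list of synthetic_recording objects, one per hour.
#' @export
synthesize_snippets <- function(config, hours, snippet_s = 90) {
  lapply(seq_along(hours), function(i) {
    cfg <- config
    cfg$duration_s <- snippet_s
    cfg$start_clock_h <- config$start_clock_h + hours[i]
    cfg$seed <- (config$seed + 104729L * i) %% .Machine$integer.max
    class(cfg) <- "sim_config"
    synthesize(cfg)
  })
}
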