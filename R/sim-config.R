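# Configuration for the synthetic two-channel LFP generator.

#' Configuration for the synthetic LFP generator
#'
#' Bundles every knob of the two-channel (vCA1-like, mPFC-like) synthetic
#' recording: vigilance-state schedule, state-dependent band amplitudes,
#' counterphase circadian modulation of the theta and gamma carrier
#' frequencies, theta-gamma phase-amplitude coupling, two-site delta phase
#' lag and jitter, sharp-wave-ripple and spindle insertion, and the 1/f^alpha
#' background.
#'
#' Defaults are the package's reference study conditions: a 512 samples/s
#' test scale, dwell means giving an NREM-dominant light phase and an
#' AWAKE-dominant dark phase with roughly 10% REM, delta near 2 Hz, theta
#' 7.5 +/- 0.4 Hz and gamma 80 -/+ 8 Hz cycling in counterphase over 24 h,
#' and band amplitudes in the hundreds-of-microvolt range.
#'
#' @param sample_rate sampling rate in samples/s (>= 256; nominal hardware
#'   rate is 2048).
#' @param duration_s recording duration in seconds.
#' @param start_clock_h clock hour at the first sample (default 6 =
#'   lights-on of a 06:00-18:00 light phase).
#' @param lights_on_h,lights_off_h light-phase boundaries in clock hours.
#' @param states vigilance states the schedule may visit (subset of
#'   AWAKE/NREM/REM; REM requires NREM).
#' @param dwell_light,dwell_dark named mean dwell times (s) per state for the
#'   light and dark phases; exponential dwells.
#' @param rem_prob probability that an NREM segment is followed by REM.
#' @param circadian list(theta_mean, theta_amp, gamma_mean, gamma_amp,
#'   period_h, phase_offset): carrier-frequency sinusoids in Hz; gamma runs
#'   pi out of phase with theta when \code{counterphase = TRUE}.
#' @param counterphase logical; gamma frequency modulation opposite to theta.
#' @param pac list(preferred_phase, coupling_depth): theta phase (rad, 0 =
#'   theta peak) at which gamma amplitude is maximal, and modulation depth in
#'   [0, 1]. Phase 0 mimics the control coupling, pi the reversed coupling.
#' @param band_amplitudes 3x3 numeric matrix (rows delta/theta/gamma, cols
#'   AWAKE/NREM/REM) of oscillation amplitudes in mV.
#' @param delta_freq,delta_freq_sd mean delta carrier frequency (Hz) and the
#'   SD of its slow per-second drift.
#' @param delta_sync list(phase_lag, phase_jitter_sd): channel-2 delta phase
#'   lag (rad) and the SD of its smooth jitter; jitter SD s gives an expected
#'   ISPC of about exp(-s^2/2).
#' @param spwr list(rate, ripple_freq, snr, duration_s): NREM
#'   sharp-wave-ripple insertion rate (events/s), ripple carrier (Hz),
#'   amplitude as a multiple of the ripple-band background RMS, and template
#'   duration.
#' @param spindle list(rate, freq, snr, duration_s, coupled_fraction,
#'   latency_mean, latency_sd): channel-2 spindle insertion; a
#'   \code{coupled_fraction} of ripples is followed by a spindle at a
#'   truncated-normal latency, the rest occur independently at \code{rate}.
#' @param pink_alpha exponent of the 1/f^alpha background.
#' @param noise_rms RMS of the background noise per channel (mV).
#' @param ch2_gain scaling of the shared theta/gamma content on channel 2.
#' @param activity list(awake_meanlog, rest_meanlog, sdlog): lognormal
#'   per-second activity-trace parameters for AWAKE vs NREM/REM seconds.
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @return validated list of class "sim_config".
#' @export
sim_config <- function(sample_rate = 512,
                       duration_s = 7200,
                       start_clock_h = 6,
                       lights_on_h = 6,
                       lights_off_h = 18,
                       states = c("AWAKE", "NREM", "REM"),
                       dwell_light = c(AWAKE = 140, NREM = 175, REM = 80),
                       dwell_dark = c(AWAKE = 240, NREM = 105, REM = 80),
                       rem_prob = 0.5,
                       circadian = list(theta_mean = 7.5, theta_amp = 0.4,
                                        gamma_mean = 80, gamma_amp = 8,
                                        period_h = 24, phase_offset = pi / 2),
                       counterphase = TRUE,
                       pac = list(preferred_phase = 0, coupling_depth = 0.6),
                       band_amplitudes = NULL,
                       delta_freq = 2.0,
                       delta_freq_sd = 0.1,
                       delta_sync = list(phase_lag = 0.25, phase_jitter_sd = 0.5),
                       spwr = list(rate = 0.44, ripple_freq = 180, snr = 6,
                                   duration_s = 0.05),
                       spindle = list(rate = 0.05, freq = 15, snr = 8,
                                      duration_s = 0.3, coupled_fraction = 0.14,
                                      latency_mean = 2.2, latency_sd = 1.5),
                       pink_alpha = 1.0,
                       noise_rms = 0.015,
                       ch2_gain = 0.6,
                       activity = list(awake_meanlog = 3, rest_meanlog = 0.5,
                                       sdlog = 0.5),
                       seed = 1L) {
  if (is.null(band_amplitudes)) {
    band_amplitudes <- matrix(
      c(0.020, 0.070, 0.020,   # delta: AWAKE, NREM, REM
        0.060, 0.015, 0.090,   # theta
        0.040, 0.010, 0.050),  # gamma
      nrow = 3, byrow = TRUE,
      dimnames = list(c("delta", "theta", "gamma"),
                      c("AWAKE", "NREM", "REM")))
  }
  cfg <- list(sample_rate = sample_rate, duration_s = duration_s,
              start_clock_h = start_clock_h, lights_on_h = lights_on_h,
              lights_off_h = lights_off_h, states = states,
              dwell_light = dwell_light, dwell_dark = dwell_dark,
              rem_prob = rem_prob, circadian = circadian,
              counterphase = counterphase, pac = pac,
              band_amplitudes = band_amplitudes, delta_freq = delta_freq,
              delta_freq_sd = delta_freq_sd, delta_sync = delta_sync,
              spwr = spwr, spindle = spindle, pink_alpha = pink_alpha,
              noise_rms = noise_rms, ch2_gain = ch2_gain,
              activity = activity, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$sample_rate < 256) stop("sample_rate must be >= 256 samples/s")
  if (cfg$duration_s <= 0) stop("duration_s must be > 0")
  if (!all(cfg$states %in% c("AWAKE", "NREM", "REM"))) {
    stop("states must be a subset of AWAKE/NREM/REM")
  }
  if ("REM" %in% cfg$states && !("NREM" %in% cfg$states)) {
    stop("REM requires NREM in the state set (REM only follows NREM)")
  }
  dw <- c(cfg$dwell_light[cfg$states], cfg$dwell_dark[cfg$states])
  if (any(!is.finite(dw)) || any(dw <= 0)) {
    stop("state dwell means must be positive for every allowed state")
  }
  d <- cfg$pac$coupling_depth
  if (d < 0 || d > 1) stop("pac coupling_depth must be in [0, 1]")
  if (any(cfg$band_amplitudes < 0)) stop("band amplitudes must be >= 0")
  if (cfg$spwr$rate < 0 || cfg$spindle$rate < 0) stop("event rates must be >= 0")
  nyq <- cfg$sample_rate / 2
  top <- max(cfg$circadian$gamma_mean + abs(cfg$circadian$gamma_amp),
             cfg$spwr$ripple_freq, cfg$spindle$freq)
  if (top >= nyq) {
    stop("requested band content (", round(top, 1),
         " Hz) is at or above the Nyquist frequency (", nyq, " Hz)")
  }
  invisible(cfg)
}

#' Light-phase indicator for recording times
#'
#' @param t_s times in seconds from the start of the recording.
#' @param config a [sim_config()] (or any list with start_clock_h,
#'   lights_on_h, lights_off_h).
#' @return logical vector, TRUE where the clock time falls in the light phase.
#' @export
is_light <- function(t_s, config) {
  h <- (config$start_clock_h + t_s / 3600) %% 24
  h >= config$lights_on_h & h < config$lights_off_h
}

# Run body with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
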