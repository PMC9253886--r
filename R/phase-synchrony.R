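# Inter-site delta-band phase synchrony.
#
# ISPC (intersite phase clustering, synonym of the phase-locking value) is
# the modulus of the mean unit phasor of the phase differences between the
# two sites: ISPC = | n^-1 sum_t exp(i (phi_x(t) - phi_y(t))) |.

#' Intersite phase clustering (phase-locking value)
#'
#' @param phi_x,phi_y phase series (rad) of the two sites on the same grid.
#' @return ISPC in [0, 1].
#' @export
#' @examples
#' ispc(rep(0.3, 100), rep(0.8, 100))  # constant offset -> 1
ispc <- function(phi_x, phi_y) {
  if (length(phi_x) != length(phi_y)) stop("phase series lengths differ")
  if (length(phi_x) < 2L) stop("need at least 2 time points")
  Mod(mean(exp(1i * (phi_x - phi_y))))
}

#' Sliding-window ISPC
#'
#' Instantaneous ISPC on a regular window grid, plus the whole-segment
#' average.
#'
#' @param phi_x,phi_y phase series (rad), same grid.
#' @param sr sample rate of the phase series (samples/s).
#' @param window_s window length in seconds (default 2, about 4 delta
#'   cycles at 2 Hz).
#' @param step_s grid step (default 0.1 s).
#' @return list(t, values, segment_ispc) with \code{t} window centers (s).
#' @export
sliding_ispc <- function(phi_x, phi_y, sr, window_s = 2, step_s = 0.1) {
  n <- length(phi_x)
  if (length(phi_y) != n) stop("phase series lengths differ")
  wl <- round(window_s * sr)
  if (wl > n) stop("window longer than the segment")
  z <- exp(1i * (phi_x - phi_y))
  cz <- cumsum(z)
  starts <- seq(1L, n - wl + 1L, by = max(1L, round(step_s * sr)))
  vals <- Mod((cz[starts + wl - 1L] - c(0i, cz)[starts]) / wl)
  list(t = (starts - 1L) / sr + window_s / 2, values = vals,
       segment_ispc = ispc(phi_x, phi_y))
}

#' Phase-difference summary with radian-to-millisecond conversion
#'
#' Histogram of the wrapped phase differences (72 bins of pi/36 over
#' (-pi, pi]) with a single-Gaussian least-squares fit of its mode; the
#' compound mean frequency is the average of the two sites' mean
#' instantaneous frequencies (from the unwrapped phases), and the lag in ms
#' is mean_rad / (2 pi f) * 1000.
#'
#' @param phi_x,phi_y phase series (rad) on the same grid.
#' @param sr sample rate of the series (samples/s); needed for the compound
#'   frequency. May be NA when \code{compound_hz} is supplied.
#' @param compound_hz optional externally determined compound frequency (Hz).
#' @param n_bins histogram bins (default 72).
#' @return list(mean_rad, lag_ms, compound_hz, histogram, fit_ok, bimodal).
#' @export
phase_diff_summary <- function(phi_x, phi_y, sr = NA, compound_hz = NULL,
                               n_bins = 72L) {
  n <- length(phi_x)
  if (n < 100L) stop("need at least 100 samples")
  dphi <- wrap_pi(phi_x - phi_y)
  br <- seq(-pi, pi, length.out = n_bins + 1L)
  hh <- graphics::hist(dphi, breaks = br, plot = FALSE)
  x <- hh$mids; y <- hh$counts
  start <- list(a = max(y), m = x[which.max(y)],
                s = max(stats::sd(dphi) / 2, pi / 36))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - m)^2 / (2 * s^2)), start = start,
                      lower = c(0, -pi, 1e-4), upper = c(Inf, pi, 2 * pi),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    mean_rad <- stats::coef(fit)[["m"]]
    res_ratio <- sqrt(mean(stats::residuals(fit)^2)) / max(y)
    bimodal <- res_ratio > 0.2
  } else {
    mean_rad <- Arg(mean(exp(1i * dphi)))   # circular-mean fallback
    bimodal <- TRUE
  }
  if (is.null(compound_hz)) {
    if (is.na(sr)) stop("supply sr or compound_hz")
    fx <- mean(diff(unwrap_phase(phi_x))) * sr / (2 * pi)
    fy <- mean(diff(unwrap_phase(phi_y))) * sr / (2 * pi)
    compound_hz <- mean(c(fx, fy))
  }
  list(mean_rad = mean_rad,
       lag_ms = rad_to_ms(mean_rad, compound_hz),
       compound_hz = compound_hz,
       histogram = data.frame(mid = x, count = y),
       fit_ok = !is.null(fit), bimodal = bimodal)
}

#' Convert a phase difference to a time lag
#'
#' @param rad phase difference in radians.
#' @param freq_hz oscillation frequency in Hz.
#' @return lag in milliseconds: rad / (2 pi freq) * 1000.
#' @export
#' @examples
#' rad_to_ms(0.792, 1.97)   # 64.0 ms
#' rad_to_ms(-0.035, 2.03)  # -2.74 ms
rad_to_ms <- function(rad, freq_hz) rad / (2 * pi * freq_hz) * 1000

#' Zero-lag cross-correlation of two filtered segments
#'
#' Pearson correlation at lag 0 between equal-length delta-filtered
#' segments (the 10-20 s segment correlation statistic).
#'
#' @param seg_x,seg_y numeric segments of equal length.
#' @return correlation coefficient.
#' @export
segment_xcorr <- function(seg_x, seg_y) {
  if (length(seg_x) != length(seg_y)) stop("segment lengths differ")
  if (stats::sd(seg_x) == 0 || stats::sd(seg_y) == 0) {
    stop("zero-variance segment")
  }
  stats::cor(seg_x, seg_y)
}

#' Delta synchrony analysis of a two-channel recording segment
#'
#' Bandpass-filters both channels in the delta band, extracts Hilbert
#' phases, and reports the segment ISPC, sliding ISPC, phase-difference
#' summary (with lag in ms) and zero-lag cross-correlation.
#'
#' @param rec recording (list with \code{channels}, \code{sample_rate}).
#' @param start_s,duration_s segment to analyse (default 120 s from 0).
#' @param edge_trim_s samples dropped at each end after filtering before
#'   phase statistics (default 1 s).
#' @return list(ispc, sliding, summary, xcorr, start_s, duration_s).
#' @export
delta_synchrony <- function(rec, start_s = 0, duration_s = 120,
                            edge_trim_s = 1) {
  sr <- rec$sample_rate
  i0 <- round(start_s * sr) + 1L
  idx <- i0:(i0 + round(duration_s * sr) - 1L)
  de <- band_edges("delta")
  spec <- filter_spec(de[1], de[2], sr)
  x <- bandpass(rec$channels[idx, 1], spec)
  y <- bandpass(rec$channels[idx, 2], spec)
  trim <- (round(edge_trim_s * sr) + 1L):(length(x) - round(edge_trim_s * sr))
  ax <- analytic_signal(x); ay <- analytic_signal(y)
  px <- ax$phase[trim]; py <- ay$phase[trim]
  list(ispc = ispc(px, py),
       sliding = sliding_ispc(px, py, sr),
       summary = phase_diff_summary(px, py, sr),
       xcorr = segment_xcorr(x[trim], y[trim]),
       start_s = start_s, duration_s = duration_s)
}
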