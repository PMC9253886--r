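# Zero-phase FIR band filtering, RMS epoch envelopes, analytic signal.
#
# The tap-count rule ties the filter length to the band width and sampling
# rate: n = int(50 / (22 * (HF - LF) / SR)), with a floor of 401 coefficients
# and an odd-length (Type-I) adjustment so the integer group delay can be
# compensated exactly, leaving no net phase shift.

#' Canonical oscillation band edges (Hz)
#'
#' Default band edges used throughout the pipeline: delta 0.5-4, theta 5-12,
#' gamma 30-120, ripple 120-250, spindle 10-30 Hz.
#'
#' @param band one of "delta", "theta", "gamma", "ripple", "spindle".
#' @return numeric length-2 vector c(low, high) in Hz.
#' @export
#' @examples
#' band_edges("theta")
band_edges <- function(band = c("delta", "theta", "gamma", "ripple", "spindle")) {
  band <- match.arg(band)
  switch(band,
    delta   = c(0.5, 4),
    theta   = c(5, 12),
    gamma   = c(30, 120),
    ripple  = c(120, 250),
    spindle = c(10, 30)
  )
}

#' Number of FIR taps for a bandpass filter
#'
#' Computes the filter length from the band edges and sampling rate as
#' \code{int(50 / (22 * (HF - LF) / SR))} (50 dB stopband, 22-unit transition
#' structure of the Hamming design rule), floored at 401 coefficients, then
#' incremented to the next odd integer so the filter is linear-phase Type I
#' with an integer group delay.
#'
#' @param lf,hf band edges in Hz, 0 < lf < hf < sr/2.
#' @param sr sampling rate in samples/s.
#' @return odd integer number of taps, >= 401.
#' @export
#' @examples
#' fir_num_taps(0.5, 4, 2048)  # 1329
#' fir_num_taps(30, 120, 2048) # 401 (floor)
fir_num_taps <- function(lf, hf, sr) {
  stopifnot(is.numeric(lf), is.numeric(hf), is.numeric(sr))
  if (!(lf > 0 && hf > lf && hf < sr / 2)) {
    stop("invalid band edges: need 0 < lf < hf < sr/2 (got lf=", lf,
         ", hf=", hf, ", sr=", sr, ")")
  }
  n <- as.integer(50 / (22 * (hf - lf) / sr))
  n <- max(401L, n)
  if (n %% 2L == 0L) n <- n + 1L
  n
}

#' Bandpass filter specification
#'
#' @param lf,hf band edges in Hz.
#' @param sr sampling rate, samples/s.
#' @param n_taps optional tap count; defaults to [fir_num_taps()]. Forced odd.
#' @return object of class "filter_spec" with fields lf, hf, sr, n_taps and
#'   the Hamming-windowed coefficient vector \code{h}.
#' @export
filter_spec <- function(lf, hf, sr, n_taps = NULL) {
  n_taps <- n_taps %||% fir_num_taps(lf, hf, sr)
  n_taps <- as.integer(n_taps)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  if (!(lf > 0 && hf > lf && hf < sr / 2)) {
    stop("invalid band edges: need 0 < lf < hf < sr/2")
  }
  h <- signal::fir1(n_taps - 1L, c(lf, hf) / (sr / 2), type = "pass")
  structure(list(lf = lf, hf = hf, sr = sr, n_taps = n_taps, h = as.numeric(h)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("FIR bandpass %.3g-%.3g Hz @ %g samples/s, %d taps (Hamming)\n",
              x$lf, x$hf, x$sr, x$n_taps))
  invisible(x)
}

#' Zero-phase FIR bandpass
#'
#' Filters a series with a linear-phase FIR bandpass and compensates the
#' integer group delay, so the output has zero net phase shift relative to
#' the input. The series is reflect-padded by one filter length before
#' convolution to suppress startup transients; output length equals input
#' length.
#'
#' @param x numeric series.
#' @param spec a [filter_spec()], or a band name accepted by [band_edges()].
#' @param sr sampling rate; required when \code{spec} is a band name.
#' @return filtered numeric series, same length as \code{x}.
#' @export
bandpass <- function(x, spec, sr = NULL) {
  if (is.character(spec)) {
    if (is.null(sr)) stop("sr is required when spec is a band name")
    e <- band_edges(spec)
    spec <- filter_spec(e[1], e[2], sr)
  }
  stopifnot(inherits(spec, "filter_spec"))
  n <- length(x)
  if (n <= spec$n_taps) {
    stop("series (length ", n, ") must be longer than the filter (",
         spec$n_taps, " taps)")
  }
  pad <- spec$n_taps
  # reflect-pad (without repeating the edge sample)
  left  <- x[(pad + 1L):2L]
  right <- x[(n - 1L):(n - pad)]
  y <- fft_convolve(c(left, x, right), spec$h)
  delay <- (spec$n_taps - 1L) %/% 2L
  y[(pad + delay + 1L):(pad + delay + n)]
}

#' RMS envelope over sliding epochs
#'
#' Root-mean-square amplitude in windows of \code{window_s} seconds centered
#' on a regular grid with \code{step_s} spacing (8 s windows stepped by 0.5
#' or 1 s for the vigilance ratios). Edge windows are truncated.
#'
#' @param x numeric series.
#' @param sr sampling rate, samples/s.
#' @param window_s window length in seconds (default 8).
#' @param step_s grid step in seconds (default 1).
#' @return object of class "envelope_series": list(values, t, window_s,
#'   step_s) with \code{t} the window-center times in seconds.
#' @export
rms_envelope <- function(x, sr, window_s = 8, step_s = 1) {
  if (step_s <= 0) stop("step_s must be > 0")
  n <- length(x)
  dur <- n / sr
  if (window_s > dur) stop("window_s (", window_s, ") exceeds series duration (",
                           round(dur, 3), " s)")
  centers <- seq(step_s / 2, dur - step_s / 2 + 1e-9, by = step_s)
  half <- window_s / 2
  cs <- cumsum(c(0, x^2))
  lo <- pmax(floor((centers - half) * sr) + 1L, 1L)
  hi <- pmin(ceiling((centers + half) * sr), n)
  vals <- sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  structure(list(values = vals, t = centers, window_s = window_s,
                 step_s = step_s), class = "envelope_series")
}

#' Analytic signal via the Hilbert transform
#'
#' Returns instantaneous amplitude and phase of a band-limited series using
#' the FFT construction of the analytic signal. Phase convention: the phase
#' of \code{cos(2*pi*f*t)} is 0 at its peaks and crosses +/-pi at troughs.
#'
#' @param x numeric series (call after [bandpass()]).
#' @return list(amplitude, phase) with phase wrapped to (-pi, pi]. An
#'   all-zero input yields zero amplitude and a \code{degenerate = TRUE} flag.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (all(x == 0)) {
    return(list(amplitude = numeric(n), phase = numeric(n), degenerate = TRUE))
  }
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1L] <- 1; w[n / 2 + 1L] <- 1
    w[2L:(n / 2)] <- 2
  } else {
    w[1L] <- 1
    w[2L:((n + 1L) / 2)] <- 2
  }
  z <- stats::fft(X * w, inverse = TRUE) / n
  list(amplitude = Mod(z), phase = Arg(z), degenerate = FALSE)
}
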