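# Whitened spectral-peak tracking.
#
# Power spectra of LFP decline as a "pink" 1/f^alpha trend; a band-limited
# oscillation is only a meaningful peak relative to that trend. For each 8 s
# window the log FFT power inside the band is smoothed, a straight line in
# log(f)-log(P) space joins the smoothed band-edge values, and the peak is
# the largest positive residual above that line ("whitening"). Peaks are
# tracked over a sliding window, averaged hourly per vigilance state, and
# summarised by fixed-period circadian sine fits and light/dark cumulative
# distributions.

#' Whitened spectral peak of one window
#'
#' @param segment numeric vector, one analysis window of raw signal.
#' @param sr sampling rate, samples/s.
#' @param band numeric c(low, high) Hz, or a band name ("theta", "gamma").
#' @param smooth_span moving-average span (bins) for in-band log-power
#'   smoothing (default 5).
#' @param floor_mult significance floor: the peak residual must exceed
#'   \code{floor_mult} times the median absolute residual of the remaining
#'   (peak-excluded) in-band bins (default 4; calibrated so pure power-law
#'   noise rarely yields a peak while in-band tones at twofold power are
#'   always kept).
#' @param edge_bins bins averaged at each band edge when anchoring the
#'   baseline (default 3; a single noisy edge bin would tilt the whole
#'   baseline).
#' @param taper apply a Hann taper before the FFT (default TRUE).
#' @return list(frequency, magnitude, present); frequency/magnitude are NA
#'   when no significant peak is present.
#' @export
whitened_peak <- function(segment, sr, band, smooth_span = 5L,
                          floor_mult = 4, edge_bins = 3L, taper = TRUE) {
  if (anyNA(segment)) stop("segment contains NA values")
  if (is.character(band)) band <- band_edges(band)
  if (band[2] >= sr / 2) stop("band extends to or beyond the Nyquist frequency")
  n <- length(segment)
  x <- segment - mean(segment)
  if (taper) x <- x * hann_window(n)
  pw <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * sr / n
  keep <- f >= band[1] & f <= band[2]
  if (sum(keep) < max(5L, smooth_span)) {
    stop("window too short to resolve the requested band")
  }
  lf <- log(f[keep])
  lp <- moving_average(log(pw[keep] + .Machine$double.xmin), smooth_span)
  # baseline: line through the smoothed band-edge values in log-log space
  nb <- length(lp)
  e <- min(edge_bins, nb %/% 2L)
  v1 <- mean(lp[seq_len(e)]);            x1 <- mean(lf[seq_len(e)])
  v2 <- mean(lp[(nb - e + 1L):nb]);      x2 <- mean(lf[(nb - e + 1L):nb])
  base <- v1 + (v2 - v1) * (lf - x1) / (x2 - x1)
  resid <- lp - base
  i <- which.max(resid)
  noise_bins <- setdiff(seq_len(nb),
                        max(1L, i - smooth_span):min(nb, i + smooth_span))
  floor_level <- floor_mult * stats::median(abs(resid[noise_bins]))
  present <- resid[i] > floor_level && resid[i] > 0
  list(frequency = if (present) f[keep][i] else NA_real_,
       magnitude = if (present) resid[i] else NA_real_,
       present = present)
}

#' Sliding-window spectral peaks over a recording channel
#'
#' 8 s windows stepped by \code{step_s} seconds; each window yields the
#' whitened theta and gamma peak frequencies (or NA) and is assigned the
#' vigilance state of the majority of its seconds (ties go to the state of
#' the earlier second).
#'
#' @param x numeric signal.
#' @param sr sampling rate.
#' @param states optional per-second state labels for window assignment.
#' @param window_s,step_s window length and step (default 8 and 1 s).
#' @param bands named list of bands (default theta and gamma edges).
#' @param ... passed to [whitened_peak()].
#' @return data.frame(window_start_s, state, theta_hz, gamma_hz) (one
#'   frequency column per requested band).
#' @export
sliding_peaks <- function(x, sr, states = NULL, window_s = 8, step_s = 1,
                          bands = list(theta = band_edges("theta"),
                                       gamma = band_edges("gamma")),
                          ...) {
  n <- length(x)
  wl <- round(window_s * sr)
  starts <- seq(0, n / sr - window_s, by = step_s)
  st <- vapply(starts, function(s0) {
    if (is.null(states)) return(NA_character_)
    secs <- as.character(states[(floor(s0) + 1):min(floor(s0) + window_s,
                                                    length(states))])
    majority_state(secs)
  }, character(1))
  res <- lapply(bands, function(bd) {
    vapply(starts, function(s0) {
      i0 <- round(s0 * sr) + 1L
      whitened_peak(x[i0:(i0 + wl - 1L)], sr, bd, ...)$frequency
    }, numeric(1))
  })
  out <- data.frame(window_start_s = starts, state = st)
  for (nm in names(res)) out[[paste0(nm, "_hz")]] <- res[[nm]]
  out
}

# Majority label; ties resolved in favour of the earliest second's label.
majority_state <- function(secs) {
  tab <- table(secs)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) return(winners)
  secs[secs %in% winners][1L]
}

#' Hourly per-state mean peak frequencies
#'
#' @param peaks a [sliding_peaks()] data.frame.
#' @param states fallback per-second labels if \code{peaks$state} is empty.
#' @return data.frame(hour, state, band, mean_hz, n_windows); hours/states
#'   without any qualifying window are absent.
#' @export
hourly_state_peaks <- function(peaks, states = NULL) {
  bands <- grep("_hz$", names(peaks), value = TRUE)
  st <- peaks$state
  if (all(is.na(st)) && !is.null(states)) {
    st <- as.character(states[floor(peaks$window_start_s) + 1L])
  }
  hour <- floor(peaks$window_start_s / 3600)
  out <- list()
  for (b in bands) {
    ok <- !is.na(peaks[[b]]) & !is.na(st)
    if (!any(ok)) next
    agg <- stats::aggregate(peaks[[b]][ok],
                            by = list(hour = hour[ok], state = st[ok]),
                            FUN = mean)
    cnt <- stats::aggregate(peaks[[b]][ok],
                            by = list(hour = hour[ok], state = st[ok]),
                            FUN = length)
    out[[b]] <- data.frame(hour = agg$hour, state = agg$state,
                           band = sub("_hz$", "", b), mean_hz = agg$x,
                           n_windows = cnt$x)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Fixed-period circadian sine fit
#'
#' Least-squares fit of \eqn{m + a sin(2 pi t / P + phi)} with the period
#' fixed (default 24 h) via the linear sin/cos parameterisation.
#'
#' @param t_h time of each value in hours.
#' @param y values (e.g. hourly mean peak frequency, Hz).
#' @param period_h fixed period (default 24).
#' @return list(mean, amplitude, phase, period_h, fitted, residual_sd,
#'   low_data) with phase in (-pi, pi]; \code{low_data} flags fewer than two
#'   full cycles of coverage.
#' @export
fit_circadian_sine <- function(t_h, y, period_h = 24) {
  ok <- is.finite(t_h) & is.finite(y)
  t_h <- t_h[ok]; y <- y[ok]
  if (length(y) < 4L) stop("need at least 4 values for a sine fit")
  # coverage counts each value's bin: 48 hourly values span two full cycles
  dt <- stats::median(diff(sort(unique(t_h))))
  low_data <- (max(t_h) - min(t_h) + dt) < 2 * period_h
  w <- 2 * pi * t_h / period_h
  fit <- stats::lm(y ~ sin(w) + cos(w))
  b <- stats::coef(fit)
  amp <- sqrt(b[2]^2 + b[3]^2)
  # a sin(w + phi) = a cos(phi) sin(w) + a sin(phi) cos(w)
  phase <- atan2(b[3], b[2])
  list(mean = unname(b[1]), amplitude = unname(amp), phase = unname(phase),
       period_h = period_h, fitted = unname(stats::fitted(fit)),
       residual_sd = stats::sd(stats::residuals(fit)), low_data = low_data)
}

#' Light/dark peak-frequency distributions and KS comparison
#'
#' Empirical cumulative distributions of peak frequencies in the light vs
#' dark phase and the two-sample Kolmogorov-Smirnov comparison (significance
#' judged at 0.001 for KS tests).
#'
#' @param freq_hz peak frequencies.
#' @param light logical, TRUE where the value belongs to the light phase.
#' @param alpha significance level for KS (default 0.001).
#' @return list(ecdf_light, ecdf_dark, statistic, p_value, significant,
#'   n_light, n_dark).
#' @export
ld_distributions <- function(freq_hz, light, alpha = 0.001) {
  ok <- is.finite(freq_hz)
  freq_hz <- freq_hz[ok]; light <- light[ok]
  a <- freq_hz[light]; b <- freq_hz[!light]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both light and dark phases must contribute peak frequencies")
  }
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(ecdf_light = stats::ecdf(a), ecdf_dark = stats::ecdf(b),
       statistic = unname(ks$statistic), p_value = ks$p.value,
       significant = ks$p.value < alpha,
       n_light = length(a), n_dark = length(b))
}
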