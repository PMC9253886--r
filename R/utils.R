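# Internal numeric helpers shared across modules.

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi)
  # %% maps exact multiples of 2*pi to 0; keep pi (not -pi) as the branch point
  y[y == 0] <- 2 * pi
  y - pi
}

#' Unwrap a phase series
#'
#' Removes 2*pi jumps so the phase is continuous; inverse of [wrap_pi()] up
#' to a constant multiple of 2*pi.
#' @param p numeric vector of wrapped phases (radians).
#' @return unwrapped phase vector.
#' @export
unwrap_phase <- function(p) {
  if (length(p) < 2L) return(p)
  d <- diff(p)
  jump <- -round(d / (2 * pi)) * 2 * pi
  p + c(0, cumsum(jump))
}

# Linear "full" convolution via FFT; returns length(x) + length(h) - 1.
fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                       stats::fft(c(h, numeric(nfft - length(h)))),
                     inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# Root mean square of a vector.
rms <- function(x) sqrt(mean(x^2))

# Centered moving average (odd span), edges truncated.
moving_average <- function(x, span) {
  if (span <= 1L) return(x)
  half <- span %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Contiguous runs of TRUE in a logical vector -> data.frame(start, end) indices.
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
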