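# Theta-gamma cross-frequency coupling.
#
# Two families of matrices over 8 s epochs:
#   FAC  - modulation index (normalised Kullback-Leibler distance of the
#          phase-conditioned gamma amplitude distribution from uniform) for
#          every theta-frequency x gamma-frequency bin pair;
#   PAC  - gamma amplitude as a function of theta phase (18 bins of pi/9 per
#          cycle, 0 rad at the theta peak), for gamma rows binned by 10 Hz
#          from 30 to 120 Hz, by two methods: per-cycle equal-time segments
#          with median peak-to-peak amplitudes, and continuous Hilbert theta
#          phase with per-bin amplitude averages.

# memoised FIR designs (fir1 of >1000 taps is not free when called per epoch)
.filter_cache <- new.env(parent = emptyenv())
cached_filter <- function(lf, hf, sr) {
  key <- paste(lf, hf, sr, sep = "|")
  sp <- .filter_cache[[key]]
  if (is.null(sp)) {
    sp <- filter_spec(lf, hf, sr)
    .filter_cache[[key]] <- sp
  }
  sp
}

#' Gamma frequency bins
#'
#' The 10 Hz-wide gamma rows of the coupling matrices. Two schemes: 9
#' non-overlapping bins spanning 30-120 Hz (default), or 14 overlapping
#' 10 Hz-wide bins with equally spaced centers over the same range.
#'
#' @param scheme "nonoverlap9" or "overlap14".
#' @return data.frame(low, high, center) in Hz.
#' @export
gamma_bins <- function(scheme = c("nonoverlap9", "overlap14")) {
  scheme <- match.arg(scheme)
  if (scheme == "nonoverlap9") {
    low <- seq(30, 110, by = 10)
  } else {
    low <- seq(30, 110, length.out = 14)
  }
  out <- data.frame(low = low, high = low + 10, center = low + 5)
  attr(out, "scheme") <- scheme
  out
}

theta_bins_default <- function() {
  low <- 5:11
  data.frame(low = low, high = low + 1, center = low + 0.5)
}

phase_bin_centers <- function(n_bins = 18L) -pi + (seq_len(n_bins) - 0.5) * 2 * pi / n_bins

#' Modulation index of phase-amplitude coupling
#'
#' Bins the amplitude series by phase (default 18 bins of pi/9), normalises
#' the per-bin mean amplitudes to a distribution P and returns the
#' Kullback-Leibler distance of P from uniform divided by log(n_bins), so
#' MI is 0 for phase-independent amplitude and 1 when all amplitude mass
#' falls in a single bin. Empty phase bins are merged into their preceding
#' neighbour and flagged.
#'
#' @param phase phase series in radians, (-pi, pi].
#' @param amplitude amplitude series, same length.
#' @param n_bins number of phase bins (default 18).
#' @return numeric MI in [0, 1] with attribute \code{merged_bins}.
#' @export
modulation_index <- function(phase, amplitude, n_bins = 18L) {
  stopifnot(length(phase) == length(amplitude))
  bin <- pmin(pmax(ceiling((phase + pi) / (2 * pi) * n_bins), 1L), n_bins)
  m <- vapply(seq_len(n_bins), function(k) {
    v <- amplitude[bin == k]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  merged <- sum(is.na(m))
  m <- m[!is.na(m)]
  nb <- length(m)
  if (nb < 2L) stop("fewer than two populated phase bins")
  p <- m / sum(m)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] * nb)) / log(nb)
  attr(mi, "merged_bins") <- merged
  mi
}

#' Surrogate test for a modulation index
#'
#' Circular time-shift surrogates: the amplitude series is rotated by random
#' offsets and the MI recomputed, giving a null distribution against which
#' the observed MI is ranked.
#'
#' @param phase,amplitude series as in [modulation_index()].
#' @param n_surrogates number of circular shifts (default 200).
#' @param n_bins phase bins.
#' @return list(mi, surrogate_q95, surrogate_q99, p_value, significant).
#' @export
mi_surrogate_test <- function(phase, amplitude, n_surrogates = 200L,
                              n_bins = 18L) {
  n <- length(amplitude)
  mi <- as.numeric(modulation_index(phase, amplitude, n_bins))
  shifts <- sample.int(n - 2L, n_surrogates, replace = TRUE)
  null_mi <- vapply(shifts, function(s) {
    as.numeric(modulation_index(phase, c(amplitude[(s + 1L):n],
                                         amplitude[seq_len(s)]), n_bins))
  }, numeric(1))
  list(mi = mi,
       surrogate_q95 = stats::quantile(null_mi, 0.95, names = FALSE),
       surrogate_q99 = stats::quantile(null_mi, 0.99, names = FALSE),
       p_value = (1 + sum(null_mi >= mi)) / (1 + n_surrogates),
       significant = mi > stats::quantile(null_mi, 0.95, names = FALSE))
}

coupling_matrix <- function(values, row_bins, col_bins, kind, n_epochs,
                            scheme = "nonoverlap9") {
  structure(list(values = values, row_bins = row_bins, col_bins = col_bins,
                 kind = kind, n_epochs = n_epochs, scheme = scheme),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("%s coupling matrix: %d gamma bins x %d columns, %d epochs (%s)\n",
              x$kind, nrow(x$values), ncol(x$values), x$n_epochs, x$scheme))
  invisible(x)
}

#' Select coupling epochs with dual spectral peaks
#'
#' Screens candidate 8 s windows of a given vigilance state and keeps those
#' in which both the theta and the gamma band show a significant whitened
#' spectral peak.
#'
#' @param x raw signal.
#' @param sr sampling rate.
#' @param states per-second labels; NULL accepts every window.
#' @param state state to sample from ("AWAKE" or "REM" typically).
#' @param n_epochs number of epochs wanted.
#' @param window_s epoch length (default 8 s).
#' @return list of numeric segments (each window_s * sr samples), possibly
#'   shorter than n_epochs when few windows qualify.
#' @export
select_coupling_epochs <- function(x, sr, states = NULL, state = "AWAKE",
                                   n_epochs = 10L, window_s = 8) {
  wl <- round(window_s * sr)
  n_s <- floor(length(x) / sr)
  cand <- seq(0, n_s - window_s, by = window_s)
  if (!is.null(states)) {
    ok <- vapply(cand, function(s0) {
      all(as.character(states[(s0 + 1):(s0 + window_s)]) == state)
    }, logical(1))
    cand <- cand[ok]
  }
  out <- list()
  for (s0 in cand) {
    seg <- x[(s0 * sr + 1L):(s0 * sr + wl)]
    th <- whitened_peak(seg, sr, "theta")
    ga <- whitened_peak(seg, sr, "gamma")
    if (th$present && ga$present) out[[length(out) + 1L]] <- seg
    if (length(out) >= n_epochs) break
  }
  out
}

check_epochs <- function(epochs, min_epochs) {
  if (length(epochs) < min_epochs) {
    stop("insufficient data: ", length(epochs), " qualifying 8 s epochs, ",
         "need at least ", min_epochs)
  }
}

#' Frequency-amplitude coupling (FAC) matrix
#'
#' For every theta-frequency x gamma-frequency bin pair, filters the epoch
#' in both narrow bands, takes the theta phase and gamma Hilbert amplitude,
#' computes the modulation index, and averages over epochs.
#'
#' @param epochs list of raw 8 s segments.
#' @param sr sampling rate.
#' @param theta_bins data.frame(low, high, center); default 1 Hz bins 5-12.
#' @param gbins gamma bins from [gamma_bins()].
#' @param min_epochs minimum epoch count (default 10).
#' @return "coupling_matrix" of MI values, rows gamma bins, columns theta bins.
#' @export
fac_matrix <- function(epochs, sr, theta_bins = theta_bins_default(),
                       gbins = gamma_bins(), min_epochs = 10L) {
  check_epochs(epochs, min_epochs)
  acc <- matrix(0, nrow(gbins), nrow(theta_bins))
  for (seg in epochs) {
    th_phase <- lapply(seq_len(nrow(theta_bins)), function(i) {
      analytic_signal(bandpass(seg, cached_filter(theta_bins$low[i],
                                                  theta_bins$high[i], sr)))$phase
    })
    g_amp <- lapply(seq_len(nrow(gbins)), function(j) {
      analytic_signal(bandpass(seg, cached_filter(gbins$low[j],
                                                  gbins$high[j], sr)))$amplitude
    })
    for (j in seq_len(nrow(gbins))) {
      for (i in seq_len(nrow(theta_bins))) {
        acc[j, i] <- acc[j, i] +
          as.numeric(modulation_index(th_phase[[i]], g_amp[[j]]))
      }
    }
  }
  coupling_matrix(acc / length(epochs), gbins$center, theta_bins$center,
                  "FAC", length(epochs), attr(gbins, "scheme") %||% "nonoverlap9")
}

# theta cycles delimited trough-to-trough from the analytic phase: a trough
# is a wrap of the phase from +pi to -pi.
theta_cycle_bounds <- function(phase, sr, lf = 5, hf = 12) {
  wraps <- which(diff(phase) < -pi)
  if (length(wraps) < 2L) return(NULL)
  len <- diff(wraps)
  ok <- len >= sr / (1.5 * hf) & len <= 1.5 * sr / lf
  cbind(start = wraps[-length(wraps)][ok] + 1L, end = wraps[-1L][ok])
}

#' PAC matrix, per-cycle method
#'
#' Isolates individual theta cycles (trough-to-trough via the analytic
#' phase), divides each cycle into 18 equal time segments of pi/9 radians,
#' measures the peak-to-peak amplitude of each 10 Hz gamma sub-band within
#' each segment, and fills the matrix with the median amplitude over cycles.
#' Columns are theta phase bins with 0 rad at the theta peak (mid-cycle).
#'
#' @inheritParams fac_matrix
#' @param n_phase_bins segments per cycle (default 18).
#' @return "coupling_matrix"; attribute \code{n_cycles} gives the number of
#'   cycles used and \code{skipped_epochs} the epochs without usable cycles.
#' @export
pac_matrix_cycles <- function(epochs, sr, gbins = gamma_bins(),
                              n_phase_bins = 18L, min_epochs = 10L) {
  check_epochs(epochs, min_epochs)
  te <- band_edges("theta")
  vals <- vector("list", nrow(gbins) * n_phase_bins)
  dim(vals) <- c(nrow(gbins), n_phase_bins)
  n_cycles <- 0L; skipped <- 0L
  for (seg in epochs) {
    th <- bandpass(seg, cached_filter(te[1], te[2], sr))
    phase <- analytic_signal(th)$phase
    cyc <- theta_cycle_bounds(phase, sr, te[1], te[2])
    if (is.null(cyc) || nrow(cyc) == 0L) { skipped <- skipped + 1L; next }
    gfilt <- lapply(seq_len(nrow(gbins)), function(j) {
      bandpass(seg, cached_filter(gbins$low[j], gbins$high[j], sr))
    })
    for (c_i in seq_len(nrow(cyc))) {
      n_cycles <- n_cycles + 1L
      idx <- cyc[c_i, "start"]:cyc[c_i, "end"]
      cuts <- round(seq(0, length(idx), length.out = n_phase_bins + 1L))
      for (k in seq_len(n_phase_bins)) {
        sl <- idx[(cuts[k] + 1L):cuts[k + 1L]]
        if (length(sl) == 0L) next
        for (j in seq_len(nrow(gbins))) {
          g <- gfilt[[j]][sl]
          vals[[j, k]] <- c(vals[[j, k]], max(g) - min(g))
        }
      }
    }
  }
  m <- matrix(vapply(vals, function(v) if (length(v)) stats::median(v) else NA_real_,
                     numeric(1)),
              nrow(gbins), n_phase_bins)
  out <- coupling_matrix(m, gbins$center, phase_bin_centers(n_phase_bins),
                         "PAC-cycles", length(epochs),
                         attr(gbins, "scheme") %||% "nonoverlap9")
  attr(out, "n_cycles") <- n_cycles
  attr(out, "skipped_epochs") <- skipped
  out
}

#' PAC matrix, continuous-Hilbert method
#'
#' Uses the continuous theta phase from the Hilbert transform of the
#' theta-filtered epoch; each 10 Hz gamma sub-band's Hilbert amplitude is
#' averaged within 18 theta-phase bins.
#'
#' @inheritParams pac_matrix_cycles
#' @return "coupling_matrix" with the same shape as [pac_matrix_cycles()].
#' @export
pac_matrix_hilbert <- function(epochs, sr, gbins = gamma_bins(),
                               n_phase_bins = 18L, min_epochs = 10L) {
  check_epochs(epochs, min_epochs)
  te <- band_edges("theta")
  acc <- matrix(0, nrow(gbins), n_phase_bins)
  cnt <- matrix(0, nrow(gbins), n_phase_bins)
  for (seg in epochs) {
    phase <- analytic_signal(bandpass(seg, cached_filter(te[1], te[2], sr)))$phase
    bin <- pmin(pmax(ceiling((phase + pi) / (2 * pi) * n_phase_bins), 1L),
                n_phase_bins)
    for (j in seq_len(nrow(gbins))) {
      amp <- analytic_signal(bandpass(seg, cached_filter(gbins$low[j],
                                                         gbins$high[j], sr)))$amplitude
      s <- tapply(amp, factor(bin, levels = seq_len(n_phase_bins)), sum)
      k <- tabulate(bin, n_phase_bins)
      s[is.na(s)] <- 0
      acc[j, ] <- acc[j, ] + as.numeric(s)
      cnt[j, ] <- cnt[j, ] + k
    }
  }
  coupling_matrix(acc / pmax(cnt, 1), gbins$center,
                  phase_bin_centers(n_phase_bins), "PAC-hilbert",
                  length(epochs), attr(gbins, "scheme") %||% "nonoverlap9")
}

#' Average, Z-score and spline-smooth coupling matrices
#'
#' Element-wise mean of a set of same-shape matrices, a Z-scored copy
#' (mean 0, SD 1 over all cells) and a bicubic-spline upsampled copy for
#' display. The raw average is retained for coordinate read-outs.
#'
#' @param matrices list of "coupling_matrix" objects of identical shape.
#' @param upsample display upsampling factor (default 4).
#' @param min_matrices minimum number required (default 10).
#' @return list(average, zscored, smoothed) - the first two are
#'   coupling_matrix objects, \code{smoothed} a plain matrix.
#' @export
average_zscore_smooth <- function(matrices, upsample = 4L, min_matrices = 10L) {
  if (length(matrices) < min_matrices) {
    stop("need at least ", min_matrices, " matrices to average")
  }
  dims <- vapply(matrices, function(m) dim(m$values), integer(2))
  if (any(dims != dims[, 1])) stop("matrix shapes differ")
  avg <- Reduce(`+`, lapply(matrices, `[[`, "values")) / length(matrices)
  z <- (avg - mean(avg)) / stats::sd(avg)
  tmpl <- matrices[[1L]]
  list(average = coupling_matrix(avg, tmpl$row_bins, tmpl$col_bins,
                                 tmpl$kind, length(matrices), tmpl$scheme),
       zscored = coupling_matrix(z, tmpl$row_bins, tmpl$col_bins,
                                 paste0(tmpl$kind, "-Z"), length(matrices),
                                 tmpl$scheme),
       smoothed = spline_upsample(avg, upsample))
}

# separable cubic-spline upsampling (rows then columns)
spline_upsample <- function(m, factor = 4L) {
  r <- nrow(m); cc <- ncol(m)
  xout_c <- seq(1, cc, length.out = cc * factor)
  tmp <- t(apply(m, 1, function(row) stats::spline(seq_len(cc), row,
                                                   xout = xout_c)$y))
  xout_r <- seq(1, r, length.out = r * factor)
  apply(tmp, 2, function(col) stats::spline(seq_len(r), col, xout = xout_r)$y)
}

#' Coordinates of maximum coupling
#'
#' Bin-center coordinates of the global maximum of a (non-Z-scored) averaged
#' coupling matrix. Ties resolve to the lowest gamma bin and earliest
#' column, with a flag.
#'
#' @param mat a "coupling_matrix".
#' @return list(row_value, col_value, row_index, col_index, tied); for PAC
#'   matrices \code{col_value} is the theta phase (rad), for FAC the theta
#'   frequency (Hz); \code{row_value} is the gamma frequency (Hz).
#' @export
max_coupling_coordinates <- function(mat) {
  v <- mat$values
  mx <- max(v, na.rm = TRUE)
  hits <- which(v == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]
  list(row_value = mat$row_bins[hits[1, 1]],
       col_value = mat$col_bins[hits[1, 2]],
       row_index = unname(hits[1, 1]), col_index = unname(hits[1, 2]),
       tied = nrow(hits) > 1L)
}

#' Preferred theta phase of a PAC matrix
#'
#' Amplitude-weighted circular mean of the phase profile (column means over
#' gamma rows), a finer-than-one-bin estimate of the coupling phase.
#'
#' @param mat a PAC "coupling_matrix".
#' @return phase in (-pi, pi].
#' @export
preferred_phase <- function(mat) {
  prof <- colMeans(mat$values, na.rm = TRUE)
  prof <- prof - min(prof)
  if (sum(prof) == 0) return(0)
  Arg(sum(prof * exp(1i * mat$col_bins)))
}
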