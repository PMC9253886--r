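# Sharp-wave-ripple and sleep-spindle detection during NREM, their coupling,
# and inter-event-interval temporal statistics.
#
# Detection: bandpass -> rectify (square then square-root) -> short RMS
# envelope -> z-score against an NREM baseline estimated iteratively with
# detected events excluded. Ripples: threshold z >= 3, event boundaries
# extended to where z returns to 0. Spindles: threshold 5 SD above the
# envelope baseline, minimum duration 5 ms.

# RMS smoothing of the rectified signal (|x| via sqrt(x^2)).
detection_envelope <- function(x, sr, smooth_s = 0.01) {
  r <- sqrt(x^2)
  w <- max(1L, round(smooth_s * sr))
  if (w %% 2L == 0L) w <- w + 1L
  sqrt(moving_average(r^2, w))
}

# Baseline over the masked samples, optionally excluding event spans.
envelope_baseline <- function(env, mask, exclude = NULL) {
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    for (r in seq_len(nrow(exclude))) {
      mask[exclude$start[r]:exclude$end[r]] <- FALSE
    }
  }
  v <- env[mask]
  list(mean = mean(v), sd = stats::sd(v))
}

# per-sample NREM mask from per-second labels
nrem_sample_mask <- function(states, sr, n) {
  sec <- pmin(floor((seq_len(n) - 1L) / sr) + 1L, length(states))
  as.character(states)[sec] == "NREM"
}

# Runs above `enter`, extended to where the series returns to `exit`,
# clipped to the NREM mask; runs separated by < min_gap_s are merged.
threshold_events <- function(z, sr, mask, enter, exit = 0,
                             min_gap_s = 0.03) {
  above <- z >= enter & mask
  if (!any(above)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  runs <- logical_runs(above)
  below_exit <- z <= exit | !mask
  # extend boundaries outwards to the exit level
  for (r in seq_len(nrow(runs))) {
    s <- runs$start[r]
    while (s > 1L && !below_exit[s - 1L]) s <- s - 1L
    e <- runs$end[r]
    while (e < length(z) && !below_exit[e + 1L]) e <- e + 1L
    runs$start[r] <- s; runs$end[r] <- e
  }
  # merge overlapping / near-coincident runs
  runs <- runs[order(runs$start), , drop = FALSE]
  gap <- round(min_gap_s * sr)
  merged <- runs[1, , drop = FALSE]
  for (r in seq_len(nrow(runs))[-1]) {
    last <- nrow(merged)
    if (runs$start[r] <= merged$end[last] + gap) {
      merged$end[last] <- max(merged$end[last], runs$end[r])
    } else {
      merged <- rbind(merged, runs[r, ])
    }
  }
  merged
}

# dominant FFT frequency of a short bandpassed event (zero-padded to >= 1 s)
event_peak_frequency <- function(seg, sr, band) {
  nfft <- max(length(seg), sr)
  pw <- Mod(stats::fft(c(seg - mean(seg), numeric(nfft - length(seg)))))^2
  f <- (seq_len(nfft) - 1) * sr / nfft
  keep <- f >= band[1] & f <= min(band[2], sr / 2)
  f[keep][which.max(pw[keep])]
}

event_train <- function(df, kind, params) {
  df <- df[order(df$onset_s), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(events = df, kind = kind, params = params),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("%s event train: %d events\n", x$kind, nrow(x$events)))
  invisible(x)
}

#' Detect sharp-wave ripples in a hippocampal channel
#'
#' Ripple-band (default 120-250 Hz) FIR bandpass, rectification, short RMS
#' envelope, z-scoring against the NREM envelope baseline; events are
#' maximal runs with z >= 3 extended to the return to z = 0, with each
#' event's dominant ripple frequency read from the FFT of its bandpassed
#' samples.
#'
#' @param x raw signal (mV).
#' @param sr sampling rate.
#' @param states per-second vigilance labels; detection is restricted to
#'   NREM.
#' @param band ripple band preset: "ripple" (120-250 Hz, default) or a
#'   numeric c(low, high). The 150-250 Hz variant used in some displays can
#'   be passed as \code{c(150, 250)}.
#' The envelope baseline (mean/SD) is estimated iteratively: a first pass
#' detects candidate events, a second pass recomputes the baseline with the
#' detected event spans excluded, and events are re-detected against the
#' refined baseline. Candidate runs shorter than \code{min_duration_ms}
#' (default 20 ms, roughly 3-4 ripple cycles) are discarded as envelope
#' noise excursions.
#'
#' @param z_enter detection threshold in z units (default 3).
#' @param smooth_s envelope RMS window (default 0.02 s).
#' @param min_gap_s events closer than this merge (default 0.03 s).
#' @param min_duration_ms minimum duration of the supra-threshold run.
#' @return "event_train" with events data.frame(onset_s, offset_s,
#'   duration_ms, peak_z, peak_freq_hz).
#' @export
detect_spwr <- function(x, sr, states, band = "ripple", z_enter = 3,
                        smooth_s = 0.02, min_gap_s = 0.03,
                        min_duration_ms = 25) {
  if (is.character(band)) band <- band_edges(band)
  band[2] <- min(band[2], sr / 2 - 1)
  params <- list(band = band, z_enter = z_enter, smooth_s = smooth_s,
                 min_gap_s = min_gap_s, min_duration_ms = min_duration_ms)
  mask <- nrem_sample_mask(states, sr, length(x))
  if (!any(mask)) {
    warning("no NREM samples: empty ripple train")
    return(event_train(empty_events(), "spwr", params))
  }
  xb <- bandpass(x, cached_filter(band[1], band[2], sr))
  env <- detection_envelope(xb, sr, smooth_s)
  bl <- envelope_baseline(env, mask)
  z <- (env - bl$mean) / bl$sd
  runs <- threshold_events(z, sr, mask, enter = z_enter, exit = 0,
                           min_gap_s = min_gap_s)
  # second pass: baseline without the detected event spans
  bl <- envelope_baseline(env, mask, exclude = runs)
  z <- (env - bl$mean) / bl$sd
  runs <- threshold_events(z, sr, mask, enter = z_enter, exit = 0,
                           min_gap_s = min_gap_s)
  core_start <- integer(nrow(runs))
  if (nrow(runs) > 0L) {
    core_ms <- vapply(seq_len(nrow(runs)), function(r) {
      idx <- runs$start[r]:runs$end[r]
      core_start[r] <<- idx[which(z[idx] >= z_enter)[1L]]
      sum(z[idx] >= z_enter) / sr * 1000
    }, numeric(1))
    keep <- core_ms >= min_duration_ms
    runs <- runs[keep, , drop = FALSE]
    core_start <- core_start[keep]
  }
  if (nrow(runs) == 0L) return(event_train(empty_events(), "spwr", params))
  ev <- data.frame(
    onset_s = (runs$start - 1L) / sr,
    offset_s = runs$end / sr,
    core_onset_s = (core_start - 1L) / sr)
  ev$duration_ms <- (ev$offset_s - ev$onset_s) * 1000
  ev$peak_z <- vapply(seq_len(nrow(runs)),
                      function(r) max(z[runs$start[r]:runs$end[r]]), numeric(1))
  ev$peak_freq_hz <- vapply(seq_len(nrow(runs)), function(r) {
    event_peak_frequency(xb[runs$start[r]:runs$end[r]], sr, band)
  }, numeric(1))
  event_train(ev, "spwr", params)
}

empty_events <- function() {
  data.frame(onset_s = numeric(0), offset_s = numeric(0),
             duration_ms = numeric(0), peak_z = numeric(0),
             peak_freq_hz = numeric(0))
}

#' Validate the sharp-wave baseline-deflection criterion
#'
#' Compares the mean of the raw trace over the event window against the
#' means of two flanking baseline windows of equal duration; the event
#' passes when both differences are within one SD of the flanking segments.
#'
#' @param event one row of an event table (onset_s, offset_s).
#' @param x raw signal.
#' @param sr sampling rate.
#' @return list(pass, diffs, sd, single_flank).
#' @export
validate_spw_baseline <- function(event, x, sr) {
  i0 <- round(event$onset_s * sr) + 1L
  i1 <- round(event$offset_s * sr)
  len <- i1 - i0 + 1L
  ev_mean <- mean(x[i0:i1])
  flanks <- list()
  if (i0 - len >= 1L) flanks$pre <- x[(i0 - len):(i0 - 1L)]
  if (i1 + len <= length(x)) flanks$post <- x[(i1 + 1L):(i1 + len)]
  if (length(flanks) == 0L) stop("event fills the whole series; no flanks")
  fl <- unlist(flanks)
  s <- stats::sd(fl)
  diffs <- vapply(flanks, function(f) abs(ev_mean - mean(f)), numeric(1))
  list(pass = all(diffs < s), diffs = diffs, sd = s,
       single_flank = length(flanks) == 1L)
}

#' Detect sleep spindles in a cortical channel
#'
#' Spindle-band (10-30 Hz) bandpass; threshold 5 SD above the baseline of
#' the rectified signal envelope; minimum event duration 5 ms (configurable
#' floor).
#'
#' The envelope dips at the zero crossings of the 10-30 Hz carrier, so runs
#' separated by less than \code{min_gap_s} (default 0.05 s, longer than a
#' half-cycle at the band centre) are merged into one event before the
#' duration floor is applied. The baseline is refined in a second pass with
#' detected event spans excluded, as for ripples.
#'
#' @inheritParams detect_spwr
#' @param sd_enter threshold in baseline SD units (default 5).
#' @param min_duration_ms minimum duration floor (default 5 ms).
#' @return "event_train" of kind "spindle".
#' @export
detect_spindles <- function(x, sr, states, band = "spindle", sd_enter = 5,
                            smooth_s = 0.03, min_duration_ms = 5,
                            min_gap_s = 0.05) {
  if (is.character(band)) band <- band_edges(band)
  params <- list(band = band, sd_enter = sd_enter, smooth_s = smooth_s,
                 min_duration_ms = min_duration_ms, min_gap_s = min_gap_s)
  mask <- nrem_sample_mask(states, sr, length(x))
  if (!any(mask)) {
    warning("no NREM samples: empty spindle train")
    return(event_train(empty_events(), "spindle", params))
  }
  xb <- bandpass(x, cached_filter(band[1], band[2], sr))
  env <- detection_envelope(xb, sr, smooth_s)
  bl <- envelope_baseline(env, mask)
  z <- (env - bl$mean) / bl$sd
  runs <- threshold_events(z, sr, mask, enter = sd_enter, exit = sd_enter,
                           min_gap_s = min_gap_s)
  bl <- envelope_baseline(env, mask, exclude = runs)
  z <- (env - bl$mean) / bl$sd
  runs <- threshold_events(z, sr, mask, enter = sd_enter, exit = sd_enter,
                           min_gap_s = min_gap_s)
  if (nrow(runs) == 0L) return(event_train(empty_events(), "spindle", params))
  dur_ms <- (runs$end - runs$start + 1L) / sr * 1000
  runs <- runs[dur_ms >= min_duration_ms, , drop = FALSE]
  if (nrow(runs) == 0L) return(event_train(empty_events(), "spindle", params))
  ev <- data.frame(onset_s = (runs$start - 1L) / sr, offset_s = runs$end / sr)
  ev$duration_ms <- (ev$offset_s - ev$onset_s) * 1000
  ev$peak_z <- vapply(seq_len(nrow(runs)),
                      function(r) max(z[runs$start[r]:runs$end[r]]), numeric(1))
  ev$peak_freq_hz <- vapply(seq_len(nrow(runs)), function(r) {
    event_peak_frequency(xb[runs$start[r]:runs$end[r]], sr, band)
  }, numeric(1))
  event_train(ev, "spindle", params)
}

#' Ripple-to-spindle coupling summary
#'
#' For each ripple, the latency to the next spindle onset; a ripple counts
#' as "followed" when that latency is within \code{window_s}. Reports the
#' fraction followed (%), the latency list and the ripple:spindle count
#' ratio.
#'
#' @param spwr,spindles "event_train" objects from the same NREM periods.
#' @param window_s coupling window in seconds (default 5).
#' @return list of class "coupling_summary": latencies (s, followed ripples
#'   only), all_latencies, fraction_followed (%), count_ratio, window_s,
#'   n_spwr, n_spindle.
#' @export
couple_events <- function(spwr, spindles, window_s = 5) {
  r_on <- spwr$events$onset_s
  s_on <- spindles$events$onset_s
  if (length(r_on) == 0L) {
    return(structure(list(latencies = numeric(0), all_latencies = numeric(0),
                          fraction_followed = 0, count_ratio = NA_real_,
                          window_s = window_s, n_spwr = 0L,
                          n_spindle = length(s_on)),
                     class = "coupling_summary"))
  }
  if (length(s_on) == 0L) {
    lat <- rep(Inf, length(r_on))
  } else {
    nxt <- findInterval(r_on, s_on) + 1L
    lat <- ifelse(nxt <= length(s_on), s_on[pmin(nxt, length(s_on))] - r_on, Inf)
  }
  followed <- is.finite(lat) & lat <= window_s
  structure(list(latencies = lat[followed],
                 all_latencies = lat[is.finite(lat)],
                 fraction_followed = 100 * mean(followed),
                 count_ratio = length(r_on) / max(length(s_on), 1L),
                 window_s = window_s,
                 n_spwr = length(r_on), n_spindle = length(s_on)),
            class = "coupling_summary")
}

#' Burstiness and memory of an inter-event-interval sequence
#'
#' Burstiness B = (sd - mean) / (sd + mean) of the IEIs: -1 for perfectly
#' regular trains, 0 for a Poisson process, towards 1 for bursty trains.
#' Memory M is the Pearson correlation of consecutive IEI pairs: positive
#' when short intervals follow short ones, negative when short and long
#' alternate.
#'
#' @param ieis inter-event intervals in seconds (>= 2; < 10 flags wide
#'   uncertainty).
#' @return list(burstiness, memory, n, flags).
#' @export
burstiness_memory <- function(ieis) {
  ieis <- ieis[is.finite(ieis)]
  n <- length(ieis)
  if (n < 2L) stop("need at least 2 inter-event intervals")
  flags <- character(0)
  if (n < 10L) flags <- c(flags, "fewer than 10 IEIs: wide uncertainty")
  m <- mean(ieis); s <- stats::sd(ieis)
  b <- (s - m) / (s + m)
  if (s == 0) {
    mem <- 0
    flags <- c(flags, "constant IEIs: memory undefined, reported as 0")
  } else {
    a <- ieis[-n]; bb <- ieis[-1L]
    if (stats::sd(a) == 0 || stats::sd(bb) == 0) {
      mem <- 0
      flags <- c(flags, "degenerate consecutive-IEI variance: memory 0")
    } else {
      mem <- stats::cor(a, bb)
    }
  }
  list(burstiness = b, memory = mem, n = n, flags = flags)
}

#' Inter-event intervals of an event train
#'
#' @param train an "event_train".
#' @return numeric vector of onset-to-onset intervals (s).
#' @export
event_ieis <- function(train) diff(train$events$onset_s)
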