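# Vigilance-state classification (AWAKE / NREM / REM) from RMS band-power
# ratios and an activity trace.
#
# Pipeline: the per-second RMS(gamma)/RMS(delta) ratio histogram over a 12 h
# block is fit by a sum of two Gaussians; the lower-mean component defines
# stepped NREM membership probabilities (1 within mean+1SD, 0.397 to
# mean+2SD, 0.067 to mean+3SD, 0 beyond); a binary NREM label follows from
# 8 s flank averaging; non-NREM seconds split into REM vs AWAKE at the
# intersection of a second two-Gaussian fit of RMS(theta)/RMS(delta), with
# REM requiring an adjacent NREM run; finally the activity trace reclassifies
# mislabelled REM/AWAKE seconds.

#' Fit a sum of two Gaussians to a value histogram
#'
#' Nonlinear least-squares fit of \eqn{w1 N(m1,s1) + w2 N(m2,s2)} (unnormalised
#' Gaussian bumps) to a 200-bin histogram spanning the 0.1-99.9 percentile
#' range, initialised from the 25th/75th percentiles. Components are returned
#' ordered by mean.
#'
#' @param values numeric vector (>= 1000 values for a stable fit).
#' @param n_bins histogram bins; NULL (default) chooses 200 for large
#'   samples and proportionally fewer below 4000 values so sparse
#'   histograms stay fittable.
#' @return list of class "gaussian_pair": components \code{low} and
#'   \code{high}, each list(mean, sd, weight); plus \code{rms_residual},
#'   \code{failed} (TRUE when the two components are not separable, in which
#'   case a single-Gaussian fallback fills both slots) and
#'   \code{variance_crossed} (TRUE when the lower-mean component does not
#'   also have the lower SD).
#' @export
fit_two_gaussians <- function(values, n_bins = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 1000L) {
    warning("two-Gaussian fit with fewer than 1000 values; results may be unstable")
  }
  n_bins <- n_bins %||% max(40L, min(200L, length(values) %/% 20L))
  qs <- stats::quantile(values, c(0.001, 0.999), names = FALSE)
  if (qs[2] <= qs[1]) qs <- range(values) + c(-1e-9, 1e-9)
  br <- seq(qs[1], qs[2], length.out = n_bins + 1L)
  hh <- graphics::hist(pmin(pmax(values, qs[1]), qs[2]), breaks = br,
                       plot = FALSE)
  x <- hh$mids; y <- hh$counts
  s0 <- max(stats::sd(values) / 2, diff(qs) / 50)
  # multi-start: quantile pairs cover balanced and strongly skewed mixtures
  starts <- lapply(list(c(0.25, 0.75), c(0.25, 0.95), c(0.05, 0.75)),
                   function(q) {
                     m <- stats::quantile(values, q, names = FALSE)
                     list(w1 = max(y), m1 = m[1], s1 = s0,
                          w2 = max(y) / 2, m2 = m[2], s2 = s0)
                   })
  fit <- NULL
  best <- Inf
  for (st in starts) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        y ~ w1 * exp(-(x - m1)^2 / (2 * s1^2)) +
            w2 * exp(-(x - m2)^2 / (2 * s2^2)),
        start = st,
        lower = c(0, qs[1], diff(qs) / 1e4, 0, qs[1], diff(qs) / 1e4),
        upper = c(Inf, qs[2], diff(qs), Inf, qs[2], diff(qs)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(cand)) next
    rss <- sum(stats::residuals(cand)^2)
    p <- as.list(stats::coef(cand))
    separated <- abs(p$m2 - p$m1) / max(abs(p$s1), abs(p$s2)) >= 0.5
    # prefer separated solutions; among them, the best residual
    score <- rss * if (separated) 1 else 1e6
    if (score < best) { best <- score; fit <- cand }
  }

  single_fallback <- function() {
    m <- mean(values); s <- stats::sd(values)
    comp <- list(mean = m, sd = s, weight = 1)
    structure(list(low = comp, high = comp, rms_residual = NA_real_,
                   failed = TRUE, variance_crossed = FALSE),
              class = "gaussian_pair")
  }
  if (is.null(fit)) return(single_fallback())
  p <- as.list(stats::coef(fit))
  # unidentifiable when the two means (or weights) collapse, or when the
  # fitted sum has no real valley between the component means (a single
  # mode split across two bumps)
  sep <- abs(p$m2 - p$m1) / max(p$s1, p$s2)
  if (!is.finite(sep) || sep < 0.5 || min(p$w1, p$w2) < 1e-6 * max(p$w1, p$w2)) {
    return(single_fallback())
  }
  # degenerate spike components carrying a negligible share of the mixture
  # mass (single-bin artefacts); genuine narrow components keep real mass
  mass <- c(abs(p$w1 * p$s1), abs(p$w2 * p$s2))
  if (min(mass) / sum(mass) < 0.02) {
    return(single_fallback())
  }
  dens <- function(v) {
    p$w1 * exp(-(v - p$m1)^2 / (2 * p$s1^2)) +
      p$w2 * exp(-(v - p$m2)^2 / (2 * p$s2^2))
  }
  grid <- seq(min(p$m1, p$m2), max(p$m1, p$m2), length.out = 64L)
  if (min(dens(grid)) > 0.85 * min(dens(p$m1), dens(p$m2))) {
    return(single_fallback())
  }
  comps <- list(list(mean = p$m1, sd = abs(p$s1), weight = p$w1),
                list(mean = p$m2, sd = abs(p$s2), weight = p$w2))
  ord <- order(c(p$m1, p$m2))
  low <- comps[[ord[1]]]; high <- comps[[ord[2]]]
  structure(list(low = low, high = high,
                 rms_residual = sqrt(mean(stats::residuals(fit)^2)),
                 failed = FALSE,
                 variance_crossed = low$sd > high$sd),
            class = "gaussian_pair")
}

#' Stepped NREM membership probability of a gamma/delta ratio
#'
#' Probability of a 1 s RMS(gamma)/RMS(delta) value belonging to the
#' lower-mean Gaussian: 1 when G/D <= mean + 1 SD, 0.397 up to mean + 2 SD,
#' 0.067 up to mean + 3 SD, and 0 beyond. The 0.397 and 0.067 weights are
#' fixed constants of the method (derived from the 68.27/95.45/99.73 normal
#' coverage fractions) and are used verbatim, not recomputed.
#'
#' @param ratio numeric vector of G/D ratios.
#' @param low lower-mean Gaussian component: list(mean, sd).
#' @return numeric vector with values in {1, 0.397, 0.067, 0}.
#' @export
nrem_probability <- function(ratio, low) {
  stopifnot(low$sd > 0)
  z <- (ratio - low$mean) / low$sd
  ifelse(z <= 1, 1, ifelse(z <= 2, 0.397, ifelse(z <= 3, 0.067, 0)))
}

#' Binary NREM labels from the probability series
#'
#' A 1 s epoch is NREM iff the mean membership probability over the 8 s
#' before it or over the 8 s after it reaches 0.5 (equivalently, it is
#' excluded only when both flanks average below 0.5). Flank windows are
#' truncated at block edges.
#'
#' @param prob numeric probability series on a 1 s grid.
#' @param flank_s flank length in seconds (default 8).
#' @return integer vector of 0/1.
#' @export
binary_nrem <- function(prob, flank_s = 8L) {
  n <- length(prob)
  cs <- cumsum(c(0, prob))
  i <- seq_len(n)
  lo <- pmax(i - flank_s, 1L)
  before <- (cs[i] - cs[lo]) / pmax(i - lo, 1L)
  before[i == 1L] <- 0                      # no preceding flank at the edge
  hi <- pmin(i + flank_s, n)
  after <- (cs[hi + 1L] - cs[i + 1L]) / pmax(hi - i, 1L)
  after[i == n] <- 0
  as.integer(before >= 0.5 | after >= 0.5)
}

#' Ratio threshold at the intersection of two Gaussians
#'
#' Solves for the point between the two component means where the weighted
#' Gaussian densities are equal (the log-density equality is a quadratic in
#' the ratio). If no root falls between the means, the SD-weighted midpoint
#' is returned with a flag.
#'
#' @param pair a [fit_two_gaussians()] result.
#' @return list(threshold, flagged).
#' @export
theta_delta_threshold <- function(pair) {
  lo <- pair$low; hi <- pair$high
  if (pair$failed || lo$mean == hi$mean) {
    stop("two-Gaussian fit did not separate; no intersection threshold exists")
  }
  # w1/s1 exp(-(x-m1)^2/2s1^2) = w2/s2 exp(-(x-m2)^2/2s2^2) in log space:
  a <- 1 / (2 * hi$sd^2) - 1 / (2 * lo$sd^2)
  b <- lo$mean / lo$sd^2 - hi$mean / hi$sd^2
  cc <- hi$mean^2 / (2 * hi$sd^2) - lo$mean^2 / (2 * lo$sd^2) +
    log(lo$weight / hi$weight)
  roots <- if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0)
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > lo$mean & roots < hi$mean]
  if (length(inside) >= 1L) {
    list(threshold = inside[1L], flagged = FALSE)
  } else {
    w <- c(lo$sd, hi$sd) / (lo$sd + hi$sd)
    list(threshold = lo$mean * w[2] + hi$mean * w[1], flagged = TRUE)
  }
}

#' Split non-NREM seconds into REM and AWAKE
#'
#' A non-NREM second is REM iff its theta/delta ratio is strictly above the
#' threshold and its run of non-NREM seconds touches an NREM run on at least
#' one side; otherwise AWAKE.
#'
#' @param theta_delta per-second RMS(theta)/RMS(delta) ratios.
#' @param nrem integer 0/1 NREM labels on the same grid.
#' @param threshold ratio threshold (strict inequality).
#' @return factor of per-second states AWAKE/NREM/REM.
#' @export
classify_rem_awake <- function(theta_delta, nrem, threshold) {
  n <- length(nrem)
  stopifnot(length(theta_delta) == n)
  state <- ifelse(nrem == 1L, "NREM", "AWAKE")
  high <- theta_delta > threshold & nrem == 0L
  runs <- logical_runs(nrem == 0L)
  for (r in seq_len(nrow(runs))) {
    s <- runs$start[r]; e <- runs$end[r]
    flanked <- (s > 1L && nrem[s - 1L] == 1L) || (e < n && nrem[e + 1L] == 1L)
    if (flanked) {
      idx <- s:e
      state[idx][high[idx]] <- "REM"
    }
  }
  factor(state, levels = c("AWAKE", "NREM", "REM"))
}

#' Activity-based reclassification of REM and AWAKE seconds
#'
#' Three passes in order: (1) REM seconds with activity strictly above the
#' pooled median activity over REM-or-AWAKE seconds become AWAKE; (2) AWAKE
#' seconds with activity strictly below the median activity over NREM
#' seconds become REM; (3) every REM run whose immediately preceding second
#' is AWAKE becomes AWAKE (no AWAKE-to-REM transitions).
#'
#' Because both the NREM probability series and the theta/delta ratio are
#' computed in 8 s epochs, state edges are smeared by up to half a window:
#' a genuine NREM-to-REM transition typically shows one to three
#' intermediate seconds that fall below the REM threshold and are labelled
#' AWAKE. Pass 3 therefore looks through transition gaps of up to
#' \code{transition_gap_s} seconds (default 4, half the ratio window): a
#' REM run is only reverted when the state beyond the gap is still AWAKE.
#'
#' @param state factor/character per-second states.
#' @param activity per-second activity trace aligned to \code{state}.
#' @param transition_gap_s AWAKE-gap tolerance (s) when checking what
#'   precedes a REM run in pass 3.
#' @return list of class "vigilance_labels": \code{state} (factor),
#'   \code{reclassified} (logical), \code{flags} (character).
#' @export
reclassify_by_activity <- function(state, activity, transition_gap_s = 4L) {
  state <- as.character(state)
  n <- length(state)
  stopifnot(length(activity) == n)
  orig <- state
  flags <- character(0)

  ra <- state %in% c("REM", "AWAKE")
  if (any(ra)) {
    med_ra <- stats::median(activity[ra])
    state[state == "REM" & activity > med_ra] <- "AWAKE"
  }
  if (any(state == "NREM")) {
    med_n <- stats::median(activity[state == "NREM"])
    state[state == "AWAKE" & activity < med_n] <- "REM"
  } else {
    flags <- c(flags, "no NREM seconds: activity pass 2 skipped")
  }
  # pass 3: REM runs preceded by AWAKE (beyond the transition-gap
  # tolerance) revert to AWAKE
  runs <- logical_runs(state == "REM")
  for (r in seq_len(nrow(runs))) {
    i <- runs$start[r] - 1L
    g <- 0L
    while (i >= 1L && state[i] == "AWAKE" && g < transition_gap_s) {
      i <- i - 1L; g <- g + 1L
    }
    if (i >= 1L && state[i] == "AWAKE") {
      state[runs$start[r]:runs$end[r]] <- "AWAKE"
    }
  }
  structure(list(state = factor(state, levels = c("AWAKE", "NREM", "REM")),
                 reclassified = state != orig, flags = flags),
            class = "vigilance_labels")
}

#' Hourly state fractions
#'
#' @param state per-second states (factor/character).
#' @return data.frame(hour, AWAKE, NREM, REM) in percent of each hour;
#'   a partial final hour is kept and flagged with attribute
#'   \code{partial_last_hour}.
#' @export
hourly_fractions <- function(state) {
  out <- schedule_hourly_fractions(state)
  attr(out, "partial_last_hour") <- (length(state) %% 3600L) != 0L
  out
}

#' Classify vigilance states of a recording
#'
#' Runs the full staging pipeline on channel 1 of a recording: band
#' filtering, 8 s RMS ratio envelopes on a 1 s grid, the two-Gaussian G/D
#' fit, stepped NREM probabilities, binary NREM labels, the theta/delta REM
#' threshold, REM/AWAKE assignment, and activity reclassification.
#'
#' @param rec a synthetic_recording or any list with \code{channels},
#'   \code{sample_rate} and \code{activity}.
#' @param channel channel used for staging (default 1).
#' @param step_s ratio grid step, 0.5 or 1 s (default 1).
#' @param activity optional per-second activity trace; defaults to
#'   \code{rec$activity}.
#' @return "vigilance_labels" with extra fields: \code{nrem_probability},
#'   \code{gd_fit}, \code{td_fit}, \code{td_threshold}, \code{ratios}.
#' @export
classify_vigilance <- function(rec, channel = 1L, step_s = 1,
                               activity = NULL) {
  sr <- rec$sample_rate
  x <- rec$channels[, channel]
  activity <- activity %||% rec$activity
  n_s <- as.integer(floor(length(x) / sr))

  flt <- function(band) bandpass(x, band, sr = sr)
  env <- function(y) rms_envelope(y, sr, window_s = 8, step_s = step_s)$values
  e_delta <- env(flt("delta"))
  e_theta <- env(flt("theta"))
  e_gamma <- env(flt("gamma"))
  gd <- e_gamma / e_delta
  td <- e_theta / e_delta

  # collapse to the 1 s grid when a 0.5 s step was used
  per_sec <- function(v) {
    if (step_s == 1) v[seq_len(n_s)]
    else {
      k <- as.integer(1 / step_s)
      colMeans(matrix(v[seq_len(n_s * k)], nrow = k))
    }
  }
  gd_s <- per_sec(gd); td_s <- per_sec(td)

  gd_fit <- fit_two_gaussians(gd_s)
  if (gd_fit$failed) warning("G/D two-Gaussian fit fell back to a single mode")
  prob <- nrem_probability(gd_s, gd_fit$low)
  nrem <- binary_nrem(prob)

  outside <- td_s[nrem == 0L]
  td_fit <- fit_two_gaussians(outside)
  if (td_fit$failed) {
    # single-mode theta/delta ratios: no REM evidence in this block
    warning("theta/delta mixture did not separate; no REM assigned")
    thr <- list(threshold = Inf, flagged = TRUE)
  } else {
    thr <- theta_delta_threshold(td_fit)
  }
  state0 <- classify_rem_awake(td_s, nrem, thr$threshold)
  out <- reclassify_by_activity(state0, activity[seq_len(n_s)])
  out$nrem_probability <- prob
  out$gd_fit <- gd_fit
  out$td_fit <- td_fit
  out$td_threshold <- thr
  out$ratios <- data.frame(second = seq_len(n_s) - 1L, gd = gd_s, td = td_s)
  out
}
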