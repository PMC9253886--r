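# Vigilance-state schedule generator: an alternating-renewal (semi-Markov)
# chain with exponential dwells whose means depend on the light/dark phase.
# Transitions: AWAKE -> NREM; NREM -> REM with probability rem_prob, else
# AWAKE; REM -> AWAKE. REM segments therefore only ever follow NREM.

#' Generate a per-second vigilance-state schedule
#'
#' Draws alternating state segments with exponentially distributed dwell
#' times. The dwell mean of each segment is taken from the light- or
#' dark-phase table according to the clock time at the segment start, which
#' produces an NREM-dominant light phase and an AWAKE-dominant dark phase.
#'
#' @param config a [sim_config()]; \code{duration_s} must be >= 60.
#' @return factor vector of length \code{duration_s} (one label per second)
#'   with levels AWAKE/NREM/REM.
#' @export
make_state_schedule <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$duration_s < 60) stop("schedule generation needs duration_s >= 60")
  with_seed(config$seed, make_state_schedule_impl(config))
}

make_state_schedule_impl <- function(config) {
  n_s <- as.integer(ceiling(config$duration_s))
  states <- config$states
  out <- character(n_s)
  t <- 0L
  # start AWAKE if allowed, otherwise the first allowed state
  cur <- if ("AWAKE" %in% states) "AWAKE" else states[[1L]]
  while (t < n_s) {
    dwell_tab <- if (is_light(t, config)) config$dwell_light else config$dwell_dark
    mean_dwell <- dwell_tab[[cur]]
    len <- max(1L, as.integer(round(stats::rexp(1L, rate = 1 / mean_dwell))))
    idx <- (t + 1L):min(t + len, n_s)
    out[idx] <- cur
    t <- t + len
    cur <- next_state(cur, states, config$rem_prob)
  }
  factor(out, levels = c("AWAKE", "NREM", "REM"))
}

next_state <- function(cur, states, rem_prob) {
  if (length(states) == 1L) return(cur)
  if (cur == "AWAKE") {
    if ("NREM" %in% states) "NREM" else "AWAKE"
  } else if (cur == "NREM") {
    if ("REM" %in% states && stats::runif(1L) < rem_prob) "REM"
    else if ("AWAKE" %in% states) "AWAKE" else "NREM"
  } else { # REM
    if ("AWAKE" %in% states) "AWAKE" else "NREM"
  }
}

#' True per-hour state fractions of a schedule
#'
#' @param states factor/character vector of per-second states.
#' @return data.frame(hour, AWAKE, NREM, REM) in percent, rows summing to 100.
#' @export
schedule_hourly_fractions <- function(states) {
  states <- factor(states, levels = c("AWAKE", "NREM", "REM"))
  hour <- (seq_along(states) - 1L) %/% 3600L
  tab <- table(hour, states)
  frac <- 100 * sweep(tab, 1, rowSums(tab), "/")
  data.frame(hour = as.integer(rownames(tab)),
             AWAKE = frac[, "AWAKE"], NREM = frac[, "NREM"],
             REM = frac[, "REM"], row.names = NULL)
}
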