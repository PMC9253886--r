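# Recording input/output and pipeline orchestration.
#
# On-disk interchange format: a flat little-endian float32 sample stream
# (channels interleaved) plus a JSON sidecar holding the sampling rate,
# channel labels, start clock time and light schedule. Labels, truth tables
# and stage outputs are plain CSV/JSON.

#' Write a recording as float32 + JSON sidecar
#'
#' @param rec recording (list with \code{channels} matrix,
#'   \code{sample_rate}, and optionally start/light metadata).
#' @param path base path; writes \code{<path>.dat} and \code{<path>.json}.
#' @return invisibly, the two file paths.
#' @export
write_recording <- function(rec, path) {
  dat <- paste0(path, ".dat"); meta <- paste0(path, ".json")
  ch <- rec$channels
  con <- file(dat, "wb")
  on.exit(close(con), add = TRUE)
  # interleaved frames, little-endian float32
  writeBin(as.numeric(t(ch)), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(sample_rate = rec$sample_rate,
         n_channels = ncol(ch),
         n_samples = nrow(ch),
         channel_labels = colnames(ch) %||% paste0("ch", seq_len(ncol(ch))),
         unit = "mV",
         start_clock_h = rec$start_clock_h %||% 6,
         lights_on_h = rec$lights_on_h %||% 6,
         lights_off_h = rec$lights_off_h %||% 18),
    meta, auto_unbox = TRUE, digits = NA)
  invisible(c(dat, meta))
}

#' Read a float32 + sidecar recording
#'
#' @param path base path as given to [write_recording()].
#' @return list(channels, sample_rate, duration_s, start_clock_h,
#'   lights_on_h, lights_off_h).
#' @export
read_recording <- function(path) {
  dat <- paste0(path, ".dat"); meta <- paste0(path, ".json")
  if (!file.exists(dat) || !file.exists(meta)) {
    stop("recording files not found at ", path, " (.dat/.json)")
  }
  info <- jsonlite::read_json(meta, simplifyVector = TRUE)
  expected <- info$n_samples * info$n_channels
  sz <- file.size(dat)
  if (sz != expected * 4L) {
    stop("truncated or inconsistent sample stream: expected ", expected * 4L,
         " bytes, found ", sz, " (difference at byte offset ",
         min(sz, expected * 4L), ")")
  }
  con <- file(dat, "rb")
  on.exit(close(con), add = TRUE)
  v <- readBin(con, numeric(), n = expected, size = 4L, endian = "little")
  ch <- matrix(v, ncol = info$n_channels, byrow = TRUE)
  colnames(ch) <- info$channel_labels
  list(channels = ch, sample_rate = info$sample_rate,
       duration_s = info$n_samples / info$sample_rate,
       start_clock_h = info$start_clock_h,
       lights_on_h = info$lights_on_h, lights_off_h = info$lights_off_h)
}

#' Write per-second truth/label tables as CSV
#'
#' @param rec a synthetic_recording.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_truth <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st_path <- file.path(dir, "truth_state.csv")
  ev_path <- file.path(dir, "truth_events.csv")
  utils::write.csv(
    data.frame(second = seq_along(rec$truth$state) - 1L,
               state = as.character(rec$truth$state),
               f_theta_hz = rec$truth$f_theta,
               f_gamma_hz = rec$truth$f_gamma,
               activity = rec$activity),
    st_path, row.names = FALSE)
  utils::write.csv(rec$truth$events, ev_path, row.names = FALSE)
  invisible(c(st_path, ev_path))
}

#' Run the full analysis pipeline on a recording
#'
#' Stage order: filtering + vigilance staging, sliding spectral peaks with
#' hourly state-conditioned averages, theta-gamma coupling (both PAC methods
#' and FAC) on screened AWAKE epochs, delta synchrony over NREM segments,
#' event detection and ripple-spindle coupling. Returns a report list; any
#' stage failure is recorded and the remaining stages still run.
#'
#' @param rec recording (synthetic or read from disk; activity trace
#'   required for staging).
#' @param coupling_epochs epochs for the coupling stage (default 10).
#' @param synchrony_segment_s delta-synchrony segment length (default 20 s).
#' @return list of class "pipeline_report" with per-stage results and a
#'   \code{failures} character vector.
#' @export
run_pipeline <- function(rec, coupling_epochs = 10L,
                         synchrony_segment_s = 20) {
  report <- list(failures = character(0))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$failures <<- c(report$failures, paste0(name, ": ",
                                                    conditionMessage(e)))
      NULL
    })
  }
  sr <- rec$sample_rate
  report$vigilance <- stage("vigilance", classify_vigilance(rec))
  states <- if (!is.null(report$vigilance)) report$vigilance$state else NULL
  report$hourly_fractions <- stage("fractions", {
    stopifnot(!is.null(states)); hourly_fractions(states)
  })
  report$peaks <- stage("peaks", {
    pk <- sliding_peaks(rec$channels[, 1], sr, states = states, step_s = 4)
    list(windows = pk, hourly = hourly_state_peaks(pk))
  })
  report$coupling <- stage("coupling", {
    ep <- select_coupling_epochs(rec$channels[, 1], sr, states, "AWAKE",
                                 n_epochs = coupling_epochs)
    pac <- pac_matrix_cycles(ep, sr, min_epochs = min(coupling_epochs,
                                                      length(ep)))
    list(pac = pac, max = max_coupling_coordinates(pac),
         preferred_phase = preferred_phase(pac))
  })
  report$synchrony <- stage("synchrony", {
    stopifnot(!is.null(states))
    runs <- logical_runs(as.character(states) == "NREM")
    runs <- runs[(runs$end - runs$start) >= synchrony_segment_s + 2, ,
                 drop = FALSE]
    if (nrow(runs) == 0L) stop("no NREM segment long enough")
    segs <- lapply(seq_len(min(5L, nrow(runs))), function(r) {
      delta_synchrony(rec, start_s = runs$start[r],
                      duration_s = synchrony_segment_s)
    })
    data.frame(start_s = vapply(segs, `[[`, numeric(1), "start_s"),
               ispc = vapply(segs, `[[`, numeric(1), "ispc"),
               xcorr = vapply(segs, `[[`, numeric(1), "xcorr"),
               dphi_rad = vapply(segs, function(s) s$summary$mean_rad,
                                 numeric(1)),
               lag_ms = vapply(segs, function(s) s$summary$lag_ms, numeric(1)))
  })
  report$events <- stage("events", {
    stopifnot(!is.null(states))
    spwr <- detect_spwr(rec$channels[, 1], sr, states)
    spn <- detect_spindles(rec$channels[, 2], sr, states)
    cs <- couple_events(spwr, spn)
    bm <- if (nrow(spwr$events) >= 3L) burstiness_memory(event_ieis(spwr))
          else NULL
    list(spwr = spwr, spindles = spn, coupling = cs, temporal = bm)
  })
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  ok <- setdiff(names(x), "failures")
  cat("pipeline report: stages", paste(ok, collapse = ", "), "\n")
  if (length(x$failures)) {
    cat("failures:\n"); for (f in x$failures) cat(" -", f, "\n")
  }
  invisible(x)
}
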