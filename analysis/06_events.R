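#!/usr/bin/env Rscript
# Sharp-wave-ripple (channel 1) and spindle (channel 2) detection during
# NREM, ripple-to-spindle coupling, and the temporal statistics of the
# ripple train (burstiness, memory), with truth-based recall/precision.
#
# Usage: Rscript analysis/06_events.R

library(lfprhythms)

out <- "results"
for (nm in c("control", "model")) {
  rec <- read_recording(file.path(out, "recordings", nm))
  labels <- read.csv(file.path(out, paste0(nm, "_labels.csv")))
  truth <- read.csv(file.path(out, "recordings", paste0(nm, "_truth"),
                              "truth_events.csv"))
  sr <- rec$sample_rate

  spwr <- detect_spwr(rec$channels[, 1], sr, labels$state)
  spn <- detect_spindles(rec$channels[, 2], sr, labels$state)
  ev <- rbind(
    data.frame(kind = "spwr", spwr$events[
      c("onset_s", "offset_s", "duration_ms", "peak_z", "peak_freq_hz")]),
    data.frame(kind = "spindle", spn$events[
      c("onset_s", "offset_s", "duration_ms", "peak_z", "peak_freq_hz")]))
  write.csv(ev, file.path(out, paste0(nm, "_events.csv")), row.names = FALSE)

  tr <- truth[truth$type == "spwr", ]
  used <- rep(FALSE, nrow(spwr$events)); hit <- 0L
  for (on in tr$onset_s) {
    j <- which(!used & abs(spwr$events$core_onset_s - on) <= 0.025)
    if (length(j)) { used[j[1]] <- TRUE; hit <- hit + 1L }
  }
  cs <- couple_events(spwr, spn, window_s = 5)
  bm <- burstiness_memory(event_ieis(spwr))
  rep <- list(n_spwr = nrow(spwr$events), n_spindle = nrow(spn$events),
              ripple_recall = hit / nrow(tr),
              mean_ripple_freq_hz = mean(spwr$events$peak_freq_hz),
              mean_ripple_duration_ms = mean(spwr$events$duration_ms),
              fraction_followed_pct = cs$fraction_followed,
              count_ratio = cs$count_ratio,
              mean_latency_s = if (length(cs$latencies)) mean(cs$latencies)
                               else NA,
              burstiness = bm$burstiness, memory = bm$memory)
  jsonlite::write_json(rep, file.path(out, paste0(nm, "_event_summary.json")),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf(paste0("%s: %d ripples (recall %.2f, %.0f Hz, %.0f ms), ",
                         "%d spindles; %.1f%% followed, ratio %.2f, ",
                         "B = %.2f, M = %.2f"),
                  nm, rep$n_spwr, rep$ripple_recall, rep$mean_ripple_freq_hz,
                  rep$mean_ripple_duration_ms, rep$n_spindle,
                  rep$fraction_followed_pct, rep$count_ratio,
                  rep$burstiness, rep$memory))
}
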