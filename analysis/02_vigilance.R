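#!/usr/bin/env Rscript
# Stage the recordings produced by 01_simulate.R: per-second AWAKE/NREM/REM
# labels from the gamma/delta ratio mixture, the theta/delta REM threshold
# and the activity trace; hourly state fractions; agreement against truth.
#
# Usage: Rscript analysis/02_vigilance.R

library(lfprhythms)

out <- "results"
for (nm in c("control", "model")) {
  rec <- read_recording(file.path(out, "recordings", nm))
  truth <- read.csv(file.path(out, "recordings", paste0(nm, "_truth"),
                              "truth_state.csv"))
  rec$activity <- truth$activity
  v <- classify_vigilance(rec)
  labels <- data.frame(second = seq_along(v$state) - 1L,
                       state = as.character(v$state),
                       nrem_probability = v$nrem_probability,
                       reclassified = v$reclassified)
  write.csv(labels, file.path(out, paste0(nm, "_labels.csv")),
            row.names = FALSE)
  write.csv(hourly_fractions(v$state),
            file.path(out, paste0(nm, "_hourly_fractions.csv")),
            row.names = FALSE)
  agree <- mean(truth$state == labels$state)
  nrem <- mean((truth$state == "NREM") == (labels$state == "NREM"))
  message(sprintf(paste0("%s: %.1f%% per-second agreement with truth, ",
                         "%.1f%% NREM-vs-rest; theta/delta threshold %.3f"),
                  nm, 100 * agree, 100 * nrem, v$td_threshold$threshold))
}
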