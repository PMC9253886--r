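#!/usr/bin/env Rscript
# Theta-gamma cross-frequency coupling on AWAKE epochs of the two staged
# recordings: PAC by both methods (per-cycle medians and continuous Hilbert
# phase), the FAC modulation-index matrix, averaged/Z-scored matrices, and
# the coordinates of maximum coupling. The control-like recording couples
# gamma to the theta peak (0 rad); the model-like recording to the trough.
#
# Usage: Rscript analysis/04_coupling.R

library(lfprhythms)

out <- "results"
long_format <- function(mat) {
  data.frame(gamma_hz = rep(mat$row_bins, ncol(mat$values)),
             column = rep(mat$col_bins, each = nrow(mat$values)),
             value = as.vector(mat$values),
             n_epochs = mat$n_epochs)
}

for (nm in c("control", "model")) {
  rec <- read_recording(file.path(out, "recordings", nm))
  labels <- read.csv(file.path(out, paste0(nm, "_labels.csv")))
  sr <- rec$sample_rate
  ep <- select_coupling_epochs(rec$channels[, 1], sr, labels$state,
                               state = "AWAKE", n_epochs = 12)
  message(nm, ": ", length(ep), " screened AWAKE epochs with dual peaks")

  pac1 <- pac_matrix_cycles(ep, sr)
  pac2 <- pac_matrix_hilbert(ep, sr)
  fac <- fac_matrix(ep, sr)
  write.csv(long_format(pac1), file.path(out, paste0(nm, "_pac_cycles.csv")),
            row.names = FALSE)
  write.csv(long_format(pac2), file.path(out, paste0(nm, "_pac_hilbert.csv")),
            row.names = FALSE)
  write.csv(long_format(fac), file.path(out, paste0(nm, "_fac.csv")),
            row.names = FALSE)

  mx1 <- max_coupling_coordinates(pac1)
  mxf <- max_coupling_coordinates(fac)
  rep <- list(
    pac_cycles_max = list(gamma_hz = mx1$row_value,
                          theta_phase_rad = mx1$col_value),
    pac_preferred_phase_cycles = preferred_phase(pac1),
    pac_preferred_phase_hilbert = preferred_phase(pac2),
    fac_max = list(gamma_hz = mxf$row_value, theta_hz = mxf$col_value))
  jsonlite::write_json(rep, file.path(out, paste0(nm, "_coupling.json")),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf(paste0("  preferred phase: cycles %.2f rad, hilbert %.2f ",
                         "rad; FAC max at theta %.1f Hz x gamma %.0f Hz"),
                  rep$pac_preferred_phase_cycles,
                  rep$pac_preferred_phase_hilbert,
                  rep$fac_max$theta_hz, rep$fac_max$gamma_hz))
}
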