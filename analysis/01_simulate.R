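#!/usr/bin/env Rscript
# Generate the two study-condition synthetic recordings: a control-like
# animal (theta-gamma coupling at the theta peak, tight delta synchrony) and
# a menopause-model-like animal (coupling reversed to the theta trough,
# degraded delta synchrony during sleep). Two hours each at the 512
# samples/s analysis scale, plus truth tables, written under results/.
#
# Usage: Rscript analysis/01_simulate.R [seed]

library(lfprhythms)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
out <- "results/recordings"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

control_cfg <- sim_config(duration_s = 7200, seed = seed,
                          pac = list(preferred_phase = 0, coupling_depth = 0.6),
                          delta_sync = list(phase_lag = 0.25,
                                            phase_jitter_sd = 0.55))
model_cfg <- sim_config(duration_s = 7200, seed = seed + 1000L,
                        pac = list(preferred_phase = pi, coupling_depth = 0.6),
                        circadian = list(theta_mean = 7.7, theta_amp = 0.4,
                                         gamma_mean = 70, gamma_amp = 8,
                                         period_h = 24, phase_offset = pi / 2),
                        delta_sync = list(phase_lag = 0.79,
                                          phase_jitter_sd = 0.95))

for (nm in c("control", "model")) {
  cfg <- if (nm == "control") control_cfg else model_cfg
  message("synthesizing ", nm, " recording (", cfg$duration_s, " s @ ",
          cfg$sample_rate, " samples/s, seed ", cfg$seed, ")")
  rec <- synthesize(cfg)
  write_recording(rec, file.path(out, nm))
  write_truth(rec, file.path(out, paste0(nm, "_truth")))
  fr <- schedule_hourly_fractions(rec$truth$state)
  message("  state fractions (%): ",
          paste(sprintf("%s %.1f", c("AWAKE", "NREM", "REM"),
                        colMeans(fr[, -1])), collapse = ", "),
          "; ", nrow(rec$truth$events), " inserted events")
}
message("recordings written to ", out)
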