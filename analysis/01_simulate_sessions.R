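#!/usr/bin/env Rscript
# Simulate a two-condition closed-loop stimulation study at desk scale:
# per subject, one "CLAS" night and one "modulated" night in which the
# generator lengthens SO half-waves and damps the up-state (the kind of
# morphology shift the stimulation protocol is designed to probe), plus a
# mixed-stage adaptation night for individual calibration. Sessions are
# written under results/sessions/ as EDF + hypnogram + ground-truth CSVs.

suppressMessages(library(soclas))

n_subjects <- 6
out_dir <- "results/sessions"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

subject_seed <- function(i, k) 10000 * i + k

night_stages <- rep(c("Wake", "N1", rep(c("N2", "N3", "N2", "REM"),
                                        times = c(4, 8, 4, 4))), 2)[1:40]

for (i in seq_len(n_subjects)) {
  # adaptation night: mixed stages for gate calibration
  adapt <- generate_session(generator_config(
    duration_s = 1200, stages = night_stages,
    so_amp_range_uv = c(-170, -120), seed = subject_seed(i, 1)))
  # CLAS condition night
  clas <- generate_session(generator_config(
    duration_s = 1200, stages = night_stages,
    so_amp_range_uv = c(-170, -120), seed = subject_seed(i, 2)))
  # modulated condition: longer half-waves, damped up-state
  amod <- generate_session(generator_config(
    duration_s = 1200, stages = night_stages,
    so_amp_range_uv = c(-170, -120),
    so_neg_dur_range_s = c(1.15, 1.55), so_pos_dur_range_s = c(0.95, 1.35),
    so_pos_frac_range = c(0.3, 0.45), seed = subject_seed(i, 3)))

  for (cond in c("adapt", "clas", "amod")) {
    s <- get(cond)
    base <- file.path(out_dir, sprintf("s%02d_%s", i, cond))
    write_edf(s$recording, paste0(base, ".edf"))
    write_hypnogram(s$hypnogram, paste0(base, ".hyp"))
    write_events(s$ground_truth$so_events, paste0(base, "_so_truth.csv"))
    write_events(s$ground_truth$spindle_events,
                 paste0(base, "_spindle_truth.csv"))
  }
  cat(sprintf("subject %d: adaptation + 2 condition nights written\n", i))
}
cat(sprintf("simulated %d subjects under %s\n", n_subjects, out_dir))
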