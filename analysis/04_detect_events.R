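#!/usr/bin/env Rscript
# Offline event detection per condition night: SOs (Moelle zero-crossing
# procedure, thresholds frozen from the CLAS night as in the study design)
# and spindles at individual peak frequencies. Writes per-session event
# tables and a per-subject summary of SO/spindle properties.

suppressMessages(library(soclas))

cfg <- session_config()
cal <- utils::read.csv("results/calibration.csv")
sess_dir <- "results/sessions"
ev_dir <- "results/events"
dir.create(ev_dir, recursive = TRUE, showWarnings = FALSE)

so_rows <- list(); sp_rows <- list()
for (subj in cal$subject) {
  # thresholds and spindle peaks frozen from the CLAS night
  rec_c <- read_recording(file.path(sess_dir, paste0(subj, "_clas.edf")))
  hyp_c <- read_hypnogram(file.path(sess_dir, paste0(subj, "_clas.hyp")))
  thr <- so_thresholds(rec_c, hyp_c, cfg)
  peaks <- suppressWarnings(estimate_spindle_peaks(rec_c, hyp_c, cfg))
  for (cond in c("clas", "amod")) {
    rec <- read_recording(file.path(sess_dir,
                                    sprintf("%s_%s.edf", subj, cond)))
    hyp <- read_hypnogram(file.path(sess_dir,
                                    sprintf("%s_%s.hyp", subj, cond)))
    so <- detect_sos(rec, hyp, cfg, thresholds = thr)
    sp <- detect_spindles(rec, hyp, peaks, cfg)
    write_events(so, file.path(ev_dir, sprintf("%s_%s_so.csv", subj, cond)))
    write_events(sp, file.path(ev_dir,
                               sprintf("%s_%s_spindles.csv", subj, cond)))
    ssum <- summarize_sos(so, hyp, cfg)
    ssum$subject <- subj; ssum$condition <- cond
    so_rows[[length(so_rows) + 1]] <- ssum
    psum <- summarize_spindles(sp, hyp, cfg)
    psum$subject <- subj; psum$condition <- cond
    sp_rows[[length(sp_rows) + 1]] <- psum
  }
}
so_tab <- do.call(rbind, so_rows)
sp_tab <- do.call(rbind, sp_rows)
utils::write.csv(so_tab, "results/so_summary.csv", row.names = FALSE)
utils::write.csv(sp_tab, "results/spindle_summary.csv", row.names = FALSE)

agg <- stats::aggregate(cbind(mean_length_s, mean_pos_peak_amp_uv,
                              pos_neg_ratio) ~ condition,
                        so_tab, mean)
print(agg)
cat("SO length and half-wave ratio by condition written to results/\n")
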