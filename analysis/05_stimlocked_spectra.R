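#!/usr/bin/env Rscript
# Stimulus-locked analyses per condition: SO-trough-locked grand averages,
# first-burst-locked ERPs with baseline normalisation, spindle RMS time
# courses, and NREM band powers. Per-subject means are written so the
# statistics stage can run paired tests on identical grids.

suppressMessages(library(soclas))

cfg <- session_config()
cal <- utils::read.csv("results/calibration.csv")
sess_dir <- "results/sessions"
dir.create("results/stimlocked", showWarnings = FALSE, recursive = TRUE)

erp_rows <- list(); band_rows <- list(); so_locked <- list()
for (subj in cal$subject) {
  for (cond in c("clas", "amod")) {
    base <- sprintf("%s_%s", subj, cond)
    rec <- read_recording(file.path(sess_dir, paste0(base, ".edf")))
    hyp <- read_hypnogram(file.path(sess_dir, paste0(base, ".hyp")))
    tr <- read_events(file.path("results/triggers",
                                paste0(base, "_triggers.csv")))
    so <- read_events(file.path("results/events", paste0(base, "_so.csv")))

    # SO-trough-locked grand average of spontaneous events
    if (nrow(so)) {
      ga <- grand_average_so(rec, so, window_s = 1.5)
      so_locked[[base]] <- data.frame(subject = subj, condition = cond,
                                      time_s = ga$time_s, mean_uv = ga$mean,
                                      sem_uv = ga$sem)
    }
    # first-burst-locked ERP, baseline-normalised
    b1 <- tr$time_s[tr$burst_index == 1]
    if (length(b1) >= 3) {
      set <- baseline_normalize(
        extract_stim_locked(rec, b1, hyp, cfg), cfg)
      erp_rows[[base]] <- data.frame(subject = subj, condition = cond,
                                     time_s = set$time_s,
                                     mean_uv = set$mean, sem_uv = set$sem,
                                     n_epochs = set$n_epochs)
    }
    # NREM band powers
    sp <- power_spectrum(rec, hyp, cfg)[[1]]
    bp <- band_powers(sp, cfg$bands_hz)
    bp$subject <- subj; bp$condition <- cond
    band_rows[[base]] <- bp
  }
}
utils::write.csv(do.call(rbind, so_locked),
                 "results/stimlocked/so_locked_means.csv", row.names = FALSE)
utils::write.csv(do.call(rbind, erp_rows),
                 "results/stimlocked/erp_means.csv", row.names = FALSE)
utils::write.csv(do.call(rbind, band_rows),
                 "results/band_powers.csv", row.names = FALSE)

bands <- do.call(rbind, band_rows)
agg <- stats::aggregate(log10_power ~ band + condition, bands, mean)
print(agg)
cat("per-subject stimulus-locked means and band powers written\n")
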