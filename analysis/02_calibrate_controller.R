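#!/usr/bin/env Rscript
# Individual calibration from each subject's adaptation night: the
# delta/theta gate threshold (histogram separation of NREM vs Wake/REM
# epoch ratios) and the SO delay (mean negative-to-positive peak interval
# of offline-detected SOs). Writes results/calibration.csv.

suppressMessages(library(soclas))

cfg <- session_config()
sess_dir <- "results/sessions"
files <- list.files(sess_dir, pattern = "_adapt\\.edf$", full.names = TRUE)
stopifnot(length(files) > 0)

rows <- lapply(files, function(f) {
  subj <- sub("_adapt\\.edf$", "", basename(f))
  rec <- read_recording(f)
  hyp <- read_hypnogram(sub("\\.edf$", ".hyp", f))
  streams <- prepare_streams(rec, cfg)
  epoch_n <- cfg$density_epoch_s * streams$fs_hz
  n_ep <- floor(length(streams$broadband) / epoch_n)
  ratios <- vapply(seq_len(n_ep), function(e)
    delta_theta_ratio(
      streams$broadband[((e - 1) * epoch_n + 1):(e * epoch_n)], cfg),
    numeric(1))
  gate <- select_dt_threshold(ratios, hyp$stages[seq_len(n_ep)])
  so <- detect_sos(rec, hyp, cfg)
  data.frame(subject = subj,
             dt_ratio_threshold = gate,
             delay_ms = individual_delay(so),
             n_so_adaptation = nrow(so))
})
cal <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
utils::write.csv(cal, "results/calibration.csv", row.names = FALSE)
print(cal)
cat(sprintf("mean gate %.1f, mean delay %.0f ms\n",
            mean(cal$dt_ratio_threshold), mean(cal$delay_ms)))
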