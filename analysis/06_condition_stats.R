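#!/usr/bin/env Rscript
# Condition comparison: running paired Wilcoxon tests along the
# SO-trough-locked time course (uncorrected and Benjamini-Hochberg masks),
# paired tests on discrete event properties, and sleep architecture.

suppressMessages(library(soclas))

so_locked <- utils::read.csv("results/stimlocked/so_locked_means.csv")
subjects <- sort(unique(so_locked$subject))
grid <- sort(unique(so_locked$time_s))

stack <- function(cond) {
  t(vapply(subjects, function(s) {
    d <- so_locked[so_locked$subject == s & so_locked$condition == cond, ]
    d$mean_uv[match(grid, d$time_s)]
  }, numeric(length(grid))))
}
res <- running_wilcoxon(stack("clas"), stack("amod"), time_s = grid)
out <- data.frame(time_s = res$time_s, p_raw = res$p_raw,
                  sig_raw = res$significant_raw,
                  sig_fdr = res$significant_fdr)
utils::write.csv(out, "results/so_locked_running_wilcoxon.csv",
                 row.names = FALSE)
cat(sprintf(
  "SO-locked traces: %d/%d points raw-significant, %d after FDR (n = %d)\n",
  sum(res$significant_raw), length(grid), sum(res$significant_fdr),
  res$n_pairs))

# discrete SO properties, paired across conditions
so_tab <- utils::read.csv("results/so_summary.csv")
props <- c("mean_length_s", "mean_pos_peak_amp_uv", "pos_neg_ratio",
           "density")
prop_rows <- lapply(props, function(p) {
  a <- so_tab[so_tab$condition == "clas", ][order(
    so_tab$subject[so_tab$condition == "clas"]), p]
  b <- so_tab[so_tab$condition == "amod", ][order(
    so_tab$subject[so_tab$condition == "amod"]), p]
  w <- wilcoxon_signed_rank(a, b)
  data.frame(property = p, mean_clas = mean(a), mean_amod = mean(b),
             W = w$statistic, p_value = w$p_value)
})
prop_tab <- do.call(rbind, prop_rows)
utils::write.csv(prop_tab, "results/so_property_tests.csv",
                 row.names = FALSE)
print(prop_tab)

# sleep architecture per session
sess_dir <- "results/sessions"
hyp_files <- list.files(sess_dir, pattern = "_(clas|amod)\\.hyp$",
                        full.names = TRUE)
arch <- do.call(rbind, lapply(hyp_files, function(f) {
  a <- sleep_architecture(read_hypnogram(f))
  data.frame(session = sub("\\.hyp$", "", basename(f)),
             TST_min = a$TST_min, WASO_min = a$WASO_min,
             efficiency_pct = a$sleep_efficiency_pct,
             REM_first_half_min = a$REM_first_half_min,
             REM_second_half_min = a$REM_second_half_min)
}))
utils::write.csv(arch, "results/sleep_architecture.csv", row.names = FALSE)
cat(sprintf("architecture: mean TST %.0f min, mean efficiency %.1f%%\n",
            mean(arch$TST_min), mean(arch$efficiency_pct)))
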