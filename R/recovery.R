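# Ground-truth recovery scoring for generator sessions. Because the
# offline detectors use relative (population-mean or SD) thresholds, the
# shallowest injected events are sub-criterion by construction; recall is
# therefore scored over the injected events that satisfy the same margin
# criterion applied to the ground-truth amplitudes.

#' SO recovery against ground truth
#'
#' Matches detected SO troughs to injected ones within `tol_s`. With
#' `margin = TRUE` (default) the denominator is restricted to injected
#' events whose trough amplitude is at or below `factor` times the mean
#' injected trough amplitude and whose peak-to-peak amplitude is at or
#' above `factor` times the injected mean, mirroring the detector's own
#' relative-threshold rule.
#'
#' @param events data frame from [detect_sos()].
#' @param ground_truth `so_events` ground-truth table from
#'   [generate_session()].
#' @param tol_s matching tolerance on trough times in seconds. Ground truth
#'   records the trough of the unfiltered injected waveform; the 0.5-Hz
#'   high-pass of the detection band displaces the filtered trough of
#'   second-long biphasic waves by up to ~0.15 s, so the default allows
#'   0.2 s.
#' @param margin restrict the denominator to margin-qualifying events.
#' @param factor relative threshold factor (the detector's 1.25).
#' @return list with `recall`, `n_matched`, `n_reference`, `n_detected`.
#' @export
so_recall <- function(events, ground_truth, tol_s = 0.2, margin = TRUE,
                      factor = 1.25) {
  gt <- ground_truth
  if (margin && nrow(gt)) {
    thr_neg <- factor * mean(gt$trough_amp_uv)
    p2p <- gt$pos_peak_amp_uv - gt$trough_amp_uv
    thr_p2p <- factor * mean(p2p)
    gt <- gt[gt$trough_amp_uv <= thr_neg & p2p >= thr_p2p, , drop = FALSE]
  }
  if (!nrow(gt))
    return(list(recall = NA_real_, n_matched = 0L, n_reference = 0L,
                n_detected = nrow(events)))
  matched <- vapply(gt$trough_time_s, function(t)
    any(abs(events$trough_time_s - t) <= tol_s), logical(1))
  list(recall = mean(matched), n_matched = sum(matched),
       n_reference = nrow(gt), n_detected = nrow(events))
}

#' Spindle recovery against ground truth
#'
#' An injected spindle counts as recovered when a detected event of the
#' same type overlaps it in time.
#'
#' @param events data frame from [detect_spindles()].
#' @param ground_truth `spindle_events` table from [generate_session()].
#' @param types spindle types to score.
#' @return list with `recall`, `n_matched`, `n_reference`, `n_detected`.
#' @export
spindle_recall <- function(events, ground_truth, types = c("slow", "fast")) {
  gt <- ground_truth[ground_truth$type %in% types, , drop = FALSE]
  ev <- events[events$type %in% types, , drop = FALSE]
  if (!nrow(gt))
    return(list(recall = NA_real_, n_matched = 0L, n_reference = 0L,
                n_detected = nrow(ev)))
  matched <- vapply(seq_len(nrow(gt)), function(i) {
    sel <- ev$type == gt$type[i]
    any(ev$start_s[sel] < gt$end_s[i] & ev$end_s[sel] > gt$start_s[i])
  }, logical(1))
  list(recall = mean(matched), n_matched = sum(matched),
       n_reference = nrow(gt), n_detected = nrow(ev))
}
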