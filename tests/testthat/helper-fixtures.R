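# Shared fixtures: all built in code at test time.

# a sim config with the planted-defect fractions switched off, so tests that
# reason about exact counts see only what they construct themselves
quiet_sim_config <- function(n_subjects = 1, seed = 1, ...) {
  sim_config(n_subjects = n_subjects, seed = seed,
             frac_unreadable = 0, frac_missing_label = 0, frac_too_short = 0,
             unknown_sex_frac = 0, invalid_bp_frac = 0, ...)
}

# bare ecg_record from a numeric vector
make_record <- function(samples, fs = 300, label = "sinus rhythm",
                        id = "REC1", subject = "S1", start = 0) {
  structure(list(record_id = id, subject_id = subject, start_time = start,
                 fs = fs, samples = samples, rhythm_label = label,
                 duration_s = length(samples) / fs),
            class = "ecg_record")
}

# minimal study stub for cleaning tests: records carry metadata only
stub_record <- function(record_id, subject_id, start_time, label = "sinus rhythm",
                        duration_s = 30) {
  list(record = list(record_id = record_id, subject_id = subject_id,
                     start_time = start_time, duration_s = duration_s,
                     rhythm_label = label))
}

# hand-built fiducial set (beats-by-waves matrices) for closed-form feature
# oracles
make_fiducials <- function(peak, onset, offset, amp, fs = 300,
                           baselines = NULL) {
  nb <- nrow(peak)
  structure(list(peak = peak, onset = onset, offset = offset, amp = amp,
                 present = !is.na(peak),
                 baselines = if (is.null(baselines)) rep(0, nb) else baselines,
                 record_id = "FID", fs = fs),
            class = "fiducial_set")
}

wave_matrix <- function(..., nb = 1) {
  m <- matrix(NA_real_, nb, 5, dimnames = list(NULL, c("P","Q","R","S","T")))
  vals <- list(...)
  for (w in names(vals)) m[, w] <- vals[[w]]
  m
}

# prediction set whose |errors| land the three BHS cumulative fractions exactly
bhs_pred <- function(frac5, frac10, frac15, n = 200) {
  k5 <- round(n * frac5); k10 <- round(n * frac10); k15 <- round(n * frac15)
  ae <- c(rep(4, k5), rep(9, k10 - k5), rep(14, k15 - k10), rep(20, n - k15))
  data.frame(y_true = rep(120, n), y_pred = 120 + ae)
}

# brute-force AUROC over all discordant/concordant pairs (independent oracle)
auroc_pairs <- function(score, label) {
  pos <- which(label == 1); neg <- which(label == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  tot / (length(pos) * length(neg))
}

# independent truth-table oracle for BP categories: evaluate the raw table
# clauses, then resolve by highest stage
bp_category_oracle <- function(sbp, dbp) {
  mapply(function(s, d) {
    hit <- c(Normal = s < 120 && d < 80,
             Elevated = s >= 120 && s <= 129 && d < 80,
             Stage1 = (s >= 130 && s <= 139) || (d >= 80 && d <= 89),
             Stage2 = s >= 140 || d >= 90)
    names(hit)[max(which(hit))]
  }, sbp, dbp)
}

# match detected against true R indices within a tolerance
rpeak_match <- function(detected, truth, tol = 3) {
  tp <- sum(vapply(truth, function(g) any(abs(detected - g) <= tol), logical(1)))
  list(sensitivity = tp / length(truth),
       ppv = sum(vapply(detected, function(d) any(abs(truth - d) <= tol),
                        logical(1))) / length(detected))
}
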