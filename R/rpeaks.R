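## R-peak detection. Energy-based detector: the record is band-limited to the
## QRS band (10-30 Hz), squared, smoothed with a moving average, thresholded
## at a fraction of a running upper quantile of the smoothed energy, and
## candidate peaks are refined to the extremum of the waveform itself under a
## 250 ms refractory period. The contract is recovery of ground-truth R
## locations on synthetic records, not any particular published algorithm.

#' Detect R peaks in a (preprocessed) ECG record
#'
#' @param record an `ecg_record`, already band-pass filtered and
#'   length-standardized.
#' @param qrs_band QRS energy band, Hz.
#' @param smooth_ms moving-average window for the energy envelope, ms.
#' @param refractory_ms minimum separation between detected peaks, ms.
#' @param threshold_frac detection threshold as a fraction of the running
#'   98th percentile of the smoothed energy.
#' @return object of class `rpeak_set`: `record_id`, `r_idx` (strictly
#'   increasing sample indices), `rr_s` (successive RR intervals, s), `fs`,
#'   and an `hr_flag` attribute when the implied HR is outside (20, 250) bpm.
#' @export
detect_r_peaks <- function(record, qrs_band = c(10, 30), smooth_ms = 120,
                           refractory_ms = 250, threshold_frac = 0.3) {
  fs <- record$fs
  x <- record$samples
  n <- length(x)
  bp <- signal::butter(2, qrs_band / (fs / 2), type = "pass")
  e <- zerophase_filter(x, bp$b, bp$a, pad = min(n - 1, round(fs)))^2
  w <- max(3L, round(smooth_ms / 1000 * fs))
  s <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  s[is.na(s)] <- 0

  # running 98th percentile: chunk-wise quantile, linearly interpolated
  chunk <- max(1L, round(3 * fs))
  starts <- seq(1L, n, by = chunk)
  qs <- vapply(starts, function(st)
    stats::quantile(s[st:min(n, st + chunk - 1L)], 0.98, names = FALSE),
    numeric(1))
  centers <- pmin(starts + chunk / 2, n)
  runq <- if (length(qs) > 1)
    stats::approx(centers, qs, xout = seq_len(n), rule = 2)$y
  else rep(qs, n)
  thr <- threshold_frac * pmax(runq, 1e-12)

  above <- s > thr
  if (!any(above)) ecgbp_stop("ecgbp_insufficient_beats",
                              "no QRS energy above threshold")
  # local maxima of the envelope among supra-threshold samples
  cand <- which(above &
                s >= c(-Inf, s[-n]) &
                s > c(s[-1], Inf))
  if (length(cand) == 0) ecgbp_stop("ecgbp_insufficient_beats", "no peaks")
  # refractory: greedy by envelope height
  refr <- round(refractory_ms / 1000 * fs)
  keep <- logical(length(cand))
  ord <- order(s[cand], decreasing = TRUE)
  taken <- integer(0)
  for (j in ord) {
    if (!length(taken) || all(abs(cand[j] - taken) >= refr)) {
      keep[j] <- TRUE
      taken <- c(taken, cand[j])
    }
  }
  cand <- sort(cand[keep])
  # refine: extremum of the waveform within +/- 80 ms
  half <- round(0.08 * fs)
  r_idx <- vapply(cand, function(c0) {
    win <- max(1L, c0 - half):min(n, c0 + half)
    win[which.max(abs(x[win]))]
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # collapse refined duplicates within the refractory period
  if (length(r_idx) > 1) {
    ok <- c(TRUE, diff(r_idx) >= refr)
    r_idx <- r_idx[ok]
  }
  if (length(r_idx) < 2)
    ecgbp_stop("ecgbp_insufficient_beats", "fewer than 2 R peaks detected")
  rr <- diff(r_idx) / fs
  out <- structure(list(record_id = record$record_id, r_idx = r_idx,
                        rr_s = rr, fs = fs),
                   class = "rpeak_set")
  hr <- 60 / mean(rr)
  if (hr <= 20 || hr >= 250) attr(out, "hr_flag") <- hr
  out
}
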