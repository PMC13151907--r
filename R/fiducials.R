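## Fiducial-point detection and the per-beat interval/amplitude/slope
## features derived from it. Waves are located as signed extrema inside
## conventional physiologic search windows relative to each R peak, clipped
## to the local RR interval; onsets/offsets are where the signal falls below
## 10% of the wave's prominence relative to the local baseline. Absent waves
## are flagged per beat, never raised. Internally a fiducial set is a stack
## of beats-by-waves matrices, which keeps the derived features vectorized.

WAVES <- c("P", "Q", "R", "S", "T")

#' Fiducial search windows
#'
#' Windows in ms relative to the R peak within which each wave's extremum is
#' searched. Conventional values; all config-exposed.
#'
#' @return named list of `c(lo, hi)` ms windows for P, Q, S, T.
#' @export
fiducial_windows <- function() {
  list(P = c(-300, -80), Q = c(-80, -10), S = c(10, 80), T = c(120, 450))
}

# walk outward from a peak; returns the first sample whose deviation from
# baseline is at or below frac of the prominence (the 10% crossing), or the
# window limit if the signal never drops that far
walk_edge <- function(x, peak_idx, baseline, prominence, limit, frac = 0.1,
                      direction = -1L) {
  thr <- frac * abs(prominence)
  i <- peak_idx
  repeat {
    nxt <- i + direction
    if ((direction < 0L && nxt < limit) || (direction > 0L && nxt > limit))
      return(i)
    if (abs(x[nxt] - baseline) <= thr) return(nxt)
    i <- nxt
  }
}

#' Detect fiducial points for every beat
#'
#' For each R peak: the local baseline is the median of the beat segment; the
#' Q and S extrema take the sign opposite to the R deflection (so inverted
#' QRS complexes resolve consistently); P and T are the largest absolute
#' deviations from baseline in their windows. A wave is flagged absent when
#' its prominence is below `presence_frac` of the R prominence.
#'
#' @param record an `ecg_record`.
#' @param rpeaks an `rpeak_set`.
#' @param windows search windows from [fiducial_windows()].
#' @param edge_frac onset/offset threshold as a fraction of peak prominence.
#' @param presence_frac minimum prominence relative to R for a wave to count
#'   as present.
#' @return object of class `fiducial_set`: beats-by-waves matrices `peak`,
#'   `onset`, `offset` (sample indices), `amp` (baseline-relative signed
#'   amplitude), `present` (logical), columns named P, Q, R, S, T, plus
#'   per-beat `baselines`, `fs`, `record_id`. Absent waves carry NA.
#' @export
detect_fiducials <- function(record, rpeaks, windows = fiducial_windows(),
                             edge_frac = 0.1, presence_frac = 0.075) {
  x <- record$samples
  fs <- record$fs
  n <- length(x)
  r_idx <- rpeaks$r_idx
  nb <- length(r_idx)
  med_rr <- stats::median(rpeaks$rr_s) * fs
  mk <- function(v) matrix(v, nb, 5, dimnames = list(NULL, WAVES))
  peak <- mk(NA_integer_); onset <- mk(NA_integer_); offset <- mk(NA_integer_)
  amp <- mk(NA_real_); present <- mk(FALSE)
  baselines <- numeric(nb)
  woff <- lapply(windows, function(w) round(w / 1000 * fs))

  for (b in seq_len(nb)) {
    r <- r_idx[b]
    rr_prev <- if (b > 1) r - r_idx[b - 1] else med_rr
    rr_next <- if (b < nb) r_idx[b + 1] - r else med_rr
    seg_lo <- max(1L, r - round(0.45 * rr_prev))
    seg_hi <- min(n, r + round(0.55 * rr_next))
    # isoelectric baseline from the pre-QRS (PR segment) region; falls back
    # to the beat-segment median when the window is unavailable
    b_lo <- max(seg_lo, r - round(0.095 * fs))
    b_hi <- max(seg_lo, r - round(0.060 * fs))
    baseline <- if (b_hi > b_lo) stats::median(x[b_lo:b_hi])
                else stats::median(x[seg_lo:seg_hi])
    baselines[b] <- baseline
    amp_r <- x[r] - baseline
    sgn_r <- if (amp_r >= 0) 1 else -1

    peak[b, "R"] <- r
    amp[b, "R"] <- amp_r
    present[b, "R"] <- TRUE
    r_lo <- max(seg_lo, r - round(0.06 * fs))
    r_hi <- min(seg_hi, r + round(0.06 * fs))
    onset[b, "R"] <- walk_edge(x, r, baseline, amp_r, r_lo, edge_frac, -1L)
    offset[b, "R"] <- walk_edge(x, r, baseline, amp_r, r_hi, edge_frac, +1L)

    for (wv in c("P", "Q", "S", "T")) {
      lo <- max(r + woff[[wv]][1], seg_lo)
      hi <- min(r + woff[[wv]][2], seg_hi)
      if (lo >= hi) next
      seg <- x[lo:hi] - baseline
      peak_rel <- if (wv %in% c("Q", "S")) {
        if (sgn_r > 0) which.min(seg) else which.max(seg)
      } else which.max(abs(seg))
      pk <- lo + peak_rel - 1L
      a <- x[pk] - baseline
      if (abs(a) < presence_frac * abs(amp_r) || amp_r == 0) next
      walk_lo <- max(seg_lo, lo - round(0.08 * fs))
      walk_hi <- min(seg_hi, hi + round(0.08 * fs))
      peak[b, wv] <- pk
      amp[b, wv] <- a
      present[b, wv] <- TRUE
      onset[b, wv] <- walk_edge(x, pk, baseline, a, walk_lo, edge_frac, -1L)
      offset[b, wv] <- walk_edge(x, pk, baseline, a, walk_hi, edge_frac, +1L)
    }
  }
  structure(list(peak = peak, onset = onset, offset = offset, amp = amp,
                 present = present, baselines = baselines,
                 record_id = record$record_id, fs = fs),
            class = "fiducial_set")
}

# segment means in O(1) per beat via a cumulative sum; i1/i2 inclusive
segment_means <- function(x, i1, i2) {
  cs <- c(0, cumsum(x))
  out <- (cs[pmin(i2, length(x)) + 1] - cs[pmax(i1, 1)]) / (i2 - i1 + 1)
  out[!is.finite(i1) | !is.finite(i2) | i2 < i1] <- NA_real_
  out
}

#' Per-beat interval features
#'
#' Intervals in ms from the standard fiducial pairs: QRS = Q onset to S
#' offset; QT = Q onset to T offset; PR = P onset to Q onset; ST = S offset
#' to T onset; peak-pair intervals (P-R, Q-R, S-R, T-R) are absolute peak
#' time differences. Segment levels are mean baseline-relative amplitudes
#' over the PR (P offset to Q onset) and ST (S offset to T onset) segments.
#' QTc uses Bazett (QT / sqrt(RR)) and Fridericia (QT / RR^(1/3)) with RR in
#' seconds; each beat uses its preceding RR (first beat: the first RR).
#'
#' @param fiducials a `fiducial_set`.
#' @param rpeaks the matching `rpeak_set`.
#' @param record the `ecg_record` (for segment levels).
#' @return data.frame, one row per beat: `qrs_dur`, `qt`, `pr_int`,
#'   `st_int`, `pr_seg_level`, `st_seg_level`, `p_r`, `q_r`, `s_r`, `t_r`,
#'   `qtc_b`, `qtc_f`. Features touching an absent wave are NA.
#' @export
interval_features <- function(fiducials, rpeaks, record) {
  fs <- fiducials$fs
  f <- fiducials
  nb <- nrow(f$peak)
  ms <- function(v) v / fs * 1000
  rr_s <- c(rpeaks$rr_s[1], rpeaks$rr_s)[seq_len(nb)]
  qt <- ms(f$offset[, "T"] - f$onset[, "Q"])
  data.frame(
    qrs_dur = ms(f$offset[, "S"] - f$onset[, "Q"]),
    qt = qt,
    pr_int = ms(f$onset[, "Q"] - f$onset[, "P"]),
    st_int = ms(f$onset[, "T"] - f$offset[, "S"]),
    pr_seg_level = segment_means(record$samples, f$offset[, "P"],
                                 f$onset[, "Q"]) - f$baselines,
    st_seg_level = segment_means(record$samples, f$offset[, "S"],
                                 f$onset[, "T"]) - f$baselines,
    p_r = abs(ms(f$peak[, "R"] - f$peak[, "P"])),
    q_r = abs(ms(f$peak[, "R"] - f$peak[, "Q"])),
    s_r = abs(ms(f$peak[, "R"] - f$peak[, "S"])),
    t_r = abs(ms(f$peak[, "R"] - f$peak[, "T"])),
    qtc_b = qt / sqrt(rr_s),
    qtc_f = qt / rr_s^(1 / 3)
  )
}

#' Per-beat amplitude and area features
#'
#' Amplitudes are signed values relative to the beat baseline; areas are the
#' plain (signed) sum of raw sample values from onset to offset inclusive.
#' Amplitude ratios `r_over_X = amp_R / amp_X` use signed amplitudes and are
#' missing when the denominator magnitude is below `eps` (never infinite).
#' `s_t_amp_diff = amp_S - amp_T`.
#'
#' @param record an `ecg_record`.
#' @param fiducials a `fiducial_set`.
#' @param eps denominator guard for ratios.
#' @return data.frame, one row per beat: `amp_p` .. `amp_t`, `area_p` ..
#'   `area_t`, `r_over_p`, `r_over_q`, `r_over_s`, `r_over_t`,
#'   `s_t_amp_diff`.
#' @export
amplitude_area_features <- function(record, fiducials, eps = 1e-6) {
  f <- fiducials
  x <- record$samples
  cs <- c(0, cumsum(x))
  area <- function(wv) {
    i1 <- f$onset[, wv]; i2 <- f$offset[, wv]
    out <- cs[i2 + 1] - cs[i1]
    out[is.na(i1) | is.na(i2) | i2 < i1] <- NA_real_
    out
  }
  ratio <- function(num, den) ifelse(is.na(den) | abs(den) < eps,
                                     NA_real_, num / den)
  a_r <- f$amp[, "R"]
  data.frame(
    amp_p = f$amp[, "P"], amp_q = f$amp[, "Q"], amp_r = a_r,
    amp_s = f$amp[, "S"], amp_t = f$amp[, "T"],
    area_p = area("P"), area_q = area("Q"), area_r = area("R"),
    area_s = area("S"), area_t = area("T"),
    r_over_p = ratio(a_r, f$amp[, "P"]), r_over_q = ratio(a_r, f$amp[, "Q"]),
    r_over_s = ratio(a_r, f$amp[, "S"]), r_over_t = ratio(a_r, f$amp[, "T"]),
    s_t_amp_diff = f$amp[, "S"] - f$amp[, "T"]
  )
}

#' Per-beat amplitude-to-timing slopes
#'
#' For each wave X in P, Q, S, T: `(amp_R - amp_X) / (t_R - t_X)` with times
#' in seconds, giving mV/s; the sign follows the signed numerator over the
#' signed time difference. Missing when either peak is absent or the times
#' coincide.
#'
#' @param fiducials a `fiducial_set`.
#' @return data.frame, one row per beat: `slope_rp`, `slope_rq`, `slope_rs`,
#'   `slope_rt`.
#' @export
slope_features <- function(fiducials) {
  f <- fiducials
  fs <- f$fs
  sl <- function(wv) {
    dt <- (f$peak[, "R"] - f$peak[, wv]) / fs
    ifelse(is.na(dt) | dt == 0, NA_real_,
           (f$amp[, "R"] - f$amp[, wv]) / dt)
  }
  data.frame(slope_rp = sl("P"), slope_rq = sl("Q"),
             slope_rs = sl("S"), slope_rt = sl("T"))
}
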