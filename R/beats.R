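## Beat stacking, robust template beats, beat SNR, and the singular-value
## beat-morphology spectrum.

#' Round up to the nearest odd integer
#' @param x numeric.
#' @return odd integer >= round-compatible with centering windows.
#' @keywords internal
odd_window <- function(x) {
  w <- floor(x / 2) * 2 + 1
  as.integer(w)
}

#' Segment beats into an R-centered matrix
#'
#' Each usable R peak contributes one row of `window_samples` samples centered
#' on the peak; beats whose window would run off either record edge are
#' dropped.
#'
#' @param record an `ecg_record`.
#' @param rpeaks an `rpeak_set`.
#' @param window_samples odd window length; defaults to the median RR
#'   interval rounded to the nearest odd sample count.
#' @return object of class `beat_matrix`: list with `beats` (matrix, one row
#'   per beat), `window_samples`, `r_idx_used`.
#' @export
segment_beats <- function(record, rpeaks, window_samples = NULL) {
  fs <- record$fs
  if (is.null(window_samples))
    window_samples <- odd_window(stats::median(rpeaks$rr_s) * fs)
  window_samples <- as.integer(window_samples)
  if (window_samples < 3 || window_samples %% 2 == 0)
    ecgbp_stop("ecgbp_config_error", "window_samples must be odd and >= 3")
  half <- (window_samples - 1L) %/% 2L
  n <- length(record$samples)
  usable <- rpeaks$r_idx[rpeaks$r_idx - half >= 1 & rpeaks$r_idx + half <= n]
  if (length(usable) == 0)
    ecgbp_stop("ecgbp_insufficient_beats", "no complete beats fit the window")
  beats <- t(vapply(usable, function(r)
    record$samples[(r - half):(r + half)], numeric(window_samples)))
  structure(list(beats = beats, window_samples = window_samples,
                 r_idx_used = usable, record_id = record$record_id),
            class = "beat_matrix")
}

#' Robust template beats: weighted average and pointwise median
#'
#' The robust weighted average (RWA) iterates a beat average with weights
#' inversely proportional to each beat's squared L2 distance from the current
#' average, so artifact beats are down-weighted; the robust beat median (RBM)
#' is the pointwise median across beats. Falls back to the plain mean (with a
#' `converged = FALSE` flag) if the iteration does not settle.
#'
#' @param beat_mat a `beat_matrix` (or bare numeric matrix).
#' @param max_iter,tol iteration cap and relative-change tolerance.
#' @return list `rwa`, `rbm`, `converged`.
#' @export
robust_average_beats <- function(beat_mat, max_iter = 10L, tol = 1e-6) {
  beats <- if (inherits(beat_mat, "beat_matrix")) beat_mat$beats else beat_mat
  if (nrow(beats) < 2)
    ecgbp_stop("ecgbp_insufficient_beats", "need >= 2 beats for templates")
  eps <- 1e-12 * max(mean(beats^2) * ncol(beats), .Machine$double.eps)
  avg <- colMeans(beats)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d2 <- rowSums((beats - matrix(avg, nrow(beats), ncol(beats),
                                  byrow = TRUE))^2)
    w <- 1 / (eps + d2)
    new_avg <- colSums(beats * w) / sum(w)
    rel <- sqrt(sum((new_avg - avg)^2) / max(sum(avg^2), .Machine$double.eps))
    avg <- new_avg
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged) avg <- colMeans(beats)
  list(rwa = avg, rbm = apply(beats, 2, stats::median), converged = converged)
}

#' Per-beat signal-to-noise ratio against template beats
#'
#' SNR of a beat is the power ratio between the beat and its residual from
#' the template beat, in dB, capped at +100 dB when the residual power falls
#' below `1e-12` of the beat power (clean recordings would otherwise produce
#' infinities). Zero-power beats are flagged missing.
#'
#' @param beat_mat a `beat_matrix` or numeric matrix.
#' @param rwa,rbm template beats from [robust_average_beats()].
#' @return data.frame `snr_rwa`, `snr_rbm` (dB; NA for zero-power beats).
#' @export
beat_snr <- function(beat_mat, rwa, rbm) {
  beats <- if (inherits(beat_mat, "beat_matrix")) beat_mat$beats else beat_mat
  p_beat <- rowMeans(beats^2)
  snr_one <- function(template) {
    resid <- beats - matrix(template, nrow(beats), ncol(beats), byrow = TRUE)
    p_res <- rowMeans(resid^2)
    out <- ifelse(p_res < 1e-12 * pmax(p_beat, .Machine$double.eps),
                  100, 10 * log10(p_beat / p_res))
    pmin(out, 100)
  }
  out <- data.frame(snr_rwa = snr_one(rwa), snr_rbm = snr_one(rbm))
  out[p_beat == 0, ] <- NA_real_
  out
}

#' Normalized singular-value beat-morphology spectrum
#'
#' Singular values of the beats-by-samples matrix, sorted descending and
#' normalized by the largest, zero-padded (or truncated) to a fixed length.
#' Identical beats give a rank-1 matrix, hence `[1, 0, 0, ...]`; morphological
#' variability spreads mass into later entries.
#'
#' @param beat_mat a `beat_matrix` or numeric matrix.
#' @param length_out fixed output length (default 45, the maximum plausible
#'   beat count in 30 s).
#' @return numeric vector of `length_out` values in `[0, 1]`, or all-NA when
#'   the matrix is all-zero.
#' @export
svd_beat_features <- function(beat_mat, length_out = 45L) {
  beats <- if (inherits(beat_mat, "beat_matrix")) beat_mat$beats else beat_mat
  if (is.null(dim(beats))) beats <- matrix(beats, nrow = 1)
  if (all(beats == 0)) return(rep(NA_real_, length_out))
  d <- svd(beats, nu = 0, nv = 0)$d
  d <- sort(d, decreasing = TRUE) / max(d)
  out <- numeric(length_out)
  k <- min(length(d), length_out)
  out[seq_len(k)] <- d[seq_len(k)]
  out
}
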