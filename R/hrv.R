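## HR/HRV summary metrics and Hjorth-style mobility/complexity.

#' Heart-rate and HRV metrics from an R-peak set
#'
#' Instantaneous HR is 60/RR (bpm); the HR sequence is summarized by mean,
#' median and 5th/95th percentiles. HRV is summarized by SDNN (sample SD of
#' RR intervals, ms) and RMSSD (root mean square of successive RR
#' differences, ms). Requires at least 3 R peaks (2 RR intervals, 1
#' successive difference); otherwise all metrics are missing.
#'
#' @param rpeaks an `rpeak_set`.
#' @return named list `hr_mean`, `hr_median`, `hr_p5`, `hr_p95`, `sdnn`,
#'   `rmssd`.
#' @export
hr_hrv_metrics <- function(rpeaks) {
  rr <- rpeaks$rr_s
  if (length(rr) < 2)
    return(list(hr_mean = NA_real_, hr_median = NA_real_, hr_p5 = NA_real_,
                hr_p95 = NA_real_, sdnn = NA_real_, rmssd = NA_real_))
  hr <- 60 / rr
  rr_ms <- rr * 1000
  list(hr_mean = mean(hr),
       hr_median = stats::median(hr),
       hr_p5 = stats::quantile(hr, 0.05, names = FALSE),
       hr_p95 = stats::quantile(hr, 0.95, names = FALSE),
       sdnn = stats::sd(rr_ms),
       rmssd = sqrt(mean(diff(rr_ms)^2)))
}

#' Signal mobility and complexity
#'
#' Variance-ratio descriptors of derivative structure, computed literally as
#' variance ratios (no square root): mobility = var(diff(x)) / var(x);
#' complexity = (var(diff2(x)) / var(diff(x))) / mobility. Derivatives are
#' first differences; variances are sample variances. Missing for (near-)
#' constant signals.
#'
#' @param x numeric signal (an `ecg_record`'s samples or a bare vector).
#' @return list `mobility`, `complexity`.
#' @export
mobility_complexity <- function(x) {
  if (inherits(x, "ecg_record")) x <- x$samples
  v0 <- stats::var(x)
  if (!is.finite(v0) || v0 < .Machine$double.eps)
    return(list(mobility = NA_real_, complexity = NA_real_))
  d1 <- diff(x); d2 <- diff(d1)
  v1 <- stats::var(d1); v2 <- stats::var(d2)
  mob <- v1 / v0
  cmp <- if (v1 < .Machine$double.eps) NA_real_ else (v2 / v1) / mob
  list(mobility = mob, complexity = cmp)
}
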