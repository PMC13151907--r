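## The interpretable ECG feature set is summarized per record into a fixed
## 128-entry vector. The exact enumeration is fixed here as the normative,
## versioned manifest: per-beat measurements are summarized across beats with
## mean/median/SD for the core measurements and mean only for derived ones
## (per-wave areas other than T, R-to-wave amplitude ratios, R-to-wave
## slopes), so that the base vector length is exactly 128:
##   21 core per-beat x 3 + 12 derived per-beat x 1 + 6 HR/HRV + 2 Hjorth
##   + 45 SVD = 128.

MANIFEST_VERSION <- "1.0"

# per-beat measurements with full mean/median/sd summaries
.per_beat_full <- c(
  snr = "snr_rwa", snr = "snr_rbm",
  interval = "qrs_dur", interval = "qt", interval = "pr_int",
  interval = "st_int", interval = "pr_seg_level", interval = "st_seg_level",
  interval = "p_r", interval = "q_r", interval = "s_r", interval = "t_r",
  interval = "qtc_b", interval = "qtc_f",
  amplitude = "amp_p", amplitude = "amp_q", amplitude = "amp_r",
  amplitude = "amp_s", amplitude = "amp_t",
  amplitude = "s_t_amp_diff", amplitude = "area_t"
)

# per-beat measurements summarized by mean only
.per_beat_mean_only <- c(
  amplitude = "area_p", amplitude = "area_q", amplitude = "area_r",
  amplitude = "area_s",
  amplitude = "r_over_p", amplitude = "r_over_q", amplitude = "r_over_s",
  amplitude = "r_over_t",
  slope = "slope_rp", slope = "slope_rq", slope = "slope_rs",
  slope = "slope_rt"
)

#' The base 128-entry ECG feature manifest
#'
#' Ordered list of feature names, feature groups and the across-beat summary
#' statistic each entry uses. The base manifest has exactly 128 entries; with
#' `include_meta = TRUE` the two supplementary inputs (mean ECG-BP time gap
#' and subject age) are appended, giving 130.
#'
#' @param include_meta append `mean_gap_s` and `age_years` (group `meta`)?
#' @return a data.frame with columns `name`, `group`, `summary_stat` and
#'   attribute `manifest_version`.
#' @export
feature_manifest <- function(include_meta = FALSE) {
  key <- if (include_meta) "meta" else "base"
  if (!is.null(.manifest_cache[[key]])) return(.manifest_cache[[key]])
  rows <- list()
  add <- function(name, group, stat) rows[[length(rows) + 1]] <<-
    data.frame(name = name, group = group, summary_stat = stat)
  for (i in seq_along(.per_beat_full)) {
    base <- .per_beat_full[[i]]; grp <- names(.per_beat_full)[i]
    for (s in c("mean", "median", "sd")) add(paste0(base, "_", s), grp, s)
  }
  for (i in seq_along(.per_beat_mean_only)) {
    add(paste0(.per_beat_mean_only[[i]], "_mean"),
        names(.per_beat_mean_only)[i], "mean")
  }
  for (nm in c("hr_mean", "hr_median", "hr_p5", "hr_p95", "sdnn", "rmssd"))
    add(nm, "hrv", "scalar")
  add("mobility", "hjorth", "scalar")
  add("complexity", "hjorth", "scalar")
  for (k in 1:45) add(sprintf("svd_%02d", k), "svd", "scalar")
  if (include_meta) {
    add("mean_gap_s", "meta", "scalar")
    add("age_years", "meta", "scalar")
  }
  out <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(out$name))
  if (!include_meta) stopifnot(nrow(out) == 128L)
  attr(out, "manifest_version") <- MANIFEST_VERSION
  .manifest_cache[[key]] <- out
  out
}

.manifest_cache <- new.env(parent = emptyenv())

#' Write the feature manifest as JSON
#'
#' @param path output file path.
#' @param manifest a manifest data.frame from [feature_manifest()].
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, manifest = feature_manifest()) {
  jsonlite::write_json(
    list(manifest_version = attr(manifest, "manifest_version"),
         features = manifest),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a feature manifest from JSON
#'
#' @param path JSON file written by [write_manifest()].
#' @return a manifest data.frame.
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- obj$features
  attr(out, "manifest_version") <- obj$manifest_version
  out
}
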