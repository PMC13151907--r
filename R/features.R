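## Feature-vector assembly: per-beat measurements are summarized across beats
## (missing-aware), scalar metrics appended, and everything ordered by the
## versioned manifest. Missing features stay NA — downstream tree learners
## must tolerate them; nothing is zero-imputed.

#' Summarize a per-beat feature across beats
#'
#' Missing-aware mean, median and sample SD. SD requires at least two finite
#' values; with none, all three are missing.
#'
#' @param values numeric per-beat values (NAs allowed).
#' @return list `mean`, `median`, `sd`.
#' @export
summarize_beatwise <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0)
    return(list(mean = NA_real_, median = NA_real_, sd = NA_real_))
  list(mean = mean(v), median = stats::median(v), sd = sd_or_na(v))
}

#' Extract the 128 interpretable ECG features from one record
#'
#' Runs the full per-record chain: R-peak detection, beat stacking with a
#' median-RR window, robust template beats and per-beat SNR, HR/HRV metrics,
#' fiducial detection and the interval/amplitude/slope features,
#' mobility/complexity, and the normalized singular-value spectrum; per-beat
#' measurements are then summarized per the manifest.
#'
#' @param record a preprocessed `ecg_record`.
#' @param manifest the base manifest from [feature_manifest()].
#' @param rpeaks optional precomputed `rpeak_set`.
#' @return named numeric vector of length `nrow(manifest)`; entries that
#'   cannot be computed are NA. Returns all-NA (with attribute `error`) when
#'   the record has too few usable beats.
#' @export
extract_record_features <- function(record, manifest = feature_manifest(),
                                    rpeaks = NULL) {
  empty <- stats::setNames(rep(NA_real_, nrow(manifest)), manifest$name)
  res <- tryCatch({
    if (is.null(rpeaks)) rpeaks <- detect_r_peaks(record)
    beats <- segment_beats(record, rpeaks)
    templ <- robust_average_beats(beats)
    snr <- beat_snr(beats, templ$rwa, templ$rbm)
    fid <- detect_fiducials(record, rpeaks)
    iv <- interval_features(fid, rpeaks, record)
    aa <- amplitude_area_features(record, fid)
    sl <- slope_features(fid)
    hrv <- hr_hrv_metrics(rpeaks)
    hj <- mobility_complexity(record$samples)
    sv <- svd_beat_features(beats)

    # per-beat series as a plain list: SNR covers beats that fit the window,
    # fiducial-derived tables cover all peaks; each is summarized on its own
    per_beat <- c(list(snr_rwa = snr$snr_rwa, snr_rbm = snr$snr_rbm),
                  as.list(iv), as.list(aa), as.list(sl))
    sums <- lapply(per_beat, summarize_beatwise)
    scalars <- c(hrv, hj,
                 stats::setNames(as.list(sv), sprintf("svd_%02d", 1:45)))

    out <- empty
    for (i in seq_len(nrow(manifest))) {
      nm <- manifest$name[i]
      stat <- manifest$summary_stat[i]
      out[i] <- if (stat == "scalar") scalars[[nm]]
        else sums[[sub(sprintf("_%s$", stat), "", nm)]][[stat]]
    }
    out
  }, ecgbp_insufficient_beats = function(e) {
    attr(empty, "error") <- conditionMessage(e)
    empty
  })
  res
}

#' Assemble the full feature vector for one paired sample
#'
#' Appends the two supplementary inputs (mean ECG-BP time gap in seconds and
#' subject age in years) to the 128 ECG features, and optionally the output
#' of an external feature plugin (a function `record -> named numeric of
#' fixed length`, e.g. a 150-feature challenge set). Plugin outputs of the
#' wrong length are a hard error.
#'
#' @param record a preprocessed `ecg_record`.
#' @param paired the record's paired-sample row (needs `mean_gap_s`,
#'   `age_years`).
#' @param manifest the base manifest.
#' @param external_plugin optional plugin function.
#' @param external_length expected plugin output length.
#' @return named numeric vector: 130 entries, or 130 + `external_length`
#'   with a plugin.
#' @export
assemble_feature_vector <- function(record, paired,
                                    manifest = feature_manifest(),
                                    external_plugin = NULL,
                                    external_length = 150L) {
  base <- extract_record_features(record, manifest)
  out <- c(base, mean_gap_s = paired$mean_gap_s, age_years = paired$age_years)
  if (!is.null(external_plugin)) {
    ext <- external_plugin(record)
    if (length(ext) != external_length)
      ecgbp_stop("ecgbp_plugin_error",
                 "external plugin returned %d values, expected %d",
                 length(ext), external_length)
    if (is.null(names(ext)) || anyDuplicated(names(ext)))
      ecgbp_stop("ecgbp_plugin_error", "plugin values must be uniquely named")
    out <- c(out, ext)
  }
  out
}

#' Extract features for every paired sample of a study
#'
#' @param study the `ecgbp_study` holding the (preprocessed) records.
#' @param paired the paired-sample table from [clean_cohort()].
#' @param manifest the base manifest.
#' @param external_plugin optional plugin, see [assemble_feature_vector()].
#' @param preprocess apply [bandpass_filter()], [notch_filter()] and
#'   [standardize_length()] before extraction?
#' @param filter_cfg a [filter_config()].
#' @return data.frame: `record_id` plus one column per feature.
#' @export
extract_features <- function(study, paired, manifest = feature_manifest(),
                             external_plugin = NULL, preprocess = TRUE,
                             filter_cfg = filter_config()) {
  recs <- stats::setNames(study$records,
                          vapply(study$records,
                                 function(r) r$record$record_id, character(1)))
  rows <- vector("list", nrow(paired))
  for (i in seq_len(nrow(paired))) {
    rec <- recs[[paired$record_id[i]]]$record
    if (preprocess) {
      rec <- standardize_length(rec)
      if (is_rejected(rec)) next
      rec <- notch_filter(bandpass_filter(rec, filter_cfg), filter_cfg)
    }
    fv <- assemble_feature_vector(rec, paired[i, ], manifest, external_plugin)
    rows[[i]] <- data.frame(record_id = paired$record_id[i], t(fv),
                            check.names = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Write a feature table to CSV
#'
#' @param features data.frame from [extract_features()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
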