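## ECG-BP pairing and cohort cleaning. Mirrors the standard workflow for
## asynchronous home-monitoring data: subject-level age/sex filters, BP
## validity screening, rhythm-label filtering, windowed pairing of each ECG
## with the average of its in-window BP readings, and per-subject capping of
## pair counts. Every excluded item carries exactly one reason code and the
## per-stage counts reconcile.

#' Cleaning configuration
#'
#' Defaults follow standard practice for ambulatory cuff-BP + ECG data:
#' adults 18-90 years, DBP 20-200 / SBP 30-300 mmHg validity ranges, a
#' 3.5-minute (210 s) pairing window either side of the ECG start (the
#' interval over which short-term BP drift stays within the 5 mmHg device
#' error margin), and at most six ECG-BP pairs per subject. All interval
#' bounds are inclusive.
#'
#' @param age_min,age_max inclusive age limits, years.
#' @param dbp_range,sbp_range inclusive validity ranges, mmHg.
#' @param window_s pairing half-window around the ECG start, seconds.
#' @param max_records_per_subject per-subject cap on retained pairs.
#' @param valid_labels rhythm labels admitted to analysis.
#' @param cap_seed seed for the random per-subject selection at the cap.
#' @return object of class `clean_config`.
#' @export
clean_config <- function(age_min = 18, age_max = 90,
                         dbp_range = c(20, 200), sbp_range = c(30, 300),
                         window_s = 210, max_records_per_subject = 6L,
                         valid_labels = valid_rhythm_labels(),
                         cap_seed = 1L) {
  if (age_min >= age_max) ecgbp_stop("ecgbp_config_error", "age_min >= age_max")
  if (window_s <= 0) ecgbp_stop("ecgbp_config_error", "window_s must be > 0")
  stopifnot(dbp_range[1] < dbp_range[2], sbp_range[1] < sbp_range[2])
  structure(list(age_min = age_min, age_max = age_max, dbp_range = dbp_range,
                 sbp_range = sbp_range, window_s = window_s,
                 max_records_per_subject = as.integer(max_records_per_subject),
                 valid_labels = valid_labels, cap_seed = cap_seed),
            class = "clean_config")
}

#' Filter ECG records by subject age and sex
#'
#' Retains records whose subject has known sex (`male`/`female`) and age
#' within `[age_min, age_max]` (inclusive) at the time of the recording.
#' Exclusions are returned with reason codes, not raised.
#'
#' @param subjects subject data.frame (`subject_id`, `sex`, `age_years`).
#' @param ecg_meta data.frame of record metadata with `record_id`,
#'   `subject_id` and optionally `age_at_record` (age at ECG time; defaults
#'   to the subject table's `age_years`).
#' @param cfg a [clean_config()].
#' @return list with `kept` (record metadata rows) and `excluded`
#'   (record_id, reason).
#' @export
filter_subjects <- function(subjects, ecg_meta, cfg = clean_config()) {
  m <- match(ecg_meta$subject_id, subjects$subject_id)
  sex <- subjects$sex[m]
  age <- if ("age_at_record" %in% names(ecg_meta)) ecg_meta$age_at_record
         else subjects$age_years[m]
  reason <- rep(NA_character_, nrow(ecg_meta))
  reason[is.na(m)] <- "unknown_subject"
  reason[is.na(reason) & (is.na(sex) | !sex %in% c("male", "female"))] <-
    "unknown_sex"
  reason[is.na(reason) & (is.na(age) | age < cfg$age_min | age > cfg$age_max)] <-
    "age_out_of_range"
  keep <- is.na(reason)
  kept <- ecg_meta[keep, , drop = FALSE]
  kept$sex <- sex[keep]
  kept$age_years <- age[keep]
  list(kept = kept,
       excluded = data.frame(record_id = ecg_meta$record_id[!keep],
                             reason = reason[!keep]))
}

#' Validate one or many BP measurements
#'
#' A reading is accepted iff DBP < SBP (strict: equal values are treated as
#' malformed) and both lie inside their inclusive validity ranges.
#'
#' @param sbp,dbp numeric vectors, mmHg.
#' @param cfg a [clean_config()].
#' @return character vector: `"accept"` or a reject reason
#'   (`"malformed"`, `"dbp_ge_sbp"`, `"sbp_out_of_range"`,
#'   `"dbp_out_of_range"`).
#' @export
validate_bp_measurement <- function(sbp, dbp, cfg = clean_config()) {
  out <- rep("accept", length(sbp))
  bad <- !is.finite(sbp) | !is.finite(dbp)
  out[bad] <- "malformed"
  i <- !bad & dbp >= sbp
  out[i] <- "dbp_ge_sbp"
  i <- out == "accept" & (sbp < cfg$sbp_range[1] | sbp > cfg$sbp_range[2])
  out[i] <- "sbp_out_of_range"
  i <- out == "accept" & (dbp < cfg$dbp_range[1] | dbp > cfg$dbp_range[2])
  out[i] <- "dbp_out_of_range"
  out
}

#' Filter ECG records by rhythm label
#'
#' Accepted iff the label is one of the configured valid labels; `unreadable`
#' and missing labels are rejected.
#'
#' @param labels character vector of rhythm labels (NA = missing).
#' @param cfg a [clean_config()].
#' @return logical vector, TRUE = accept.
#' @export
filter_ecg_labels <- function(labels, cfg = clean_config()) {
  !is.na(labels) & labels %in% cfg$valid_labels
}

#' Pair one ECG with its windowed BP average
#'
#' All validated BP readings of the subject within `[t - window_s,
#' t + window_s]` (inclusive, anchored at the ECG start `t`) are averaged
#' arithmetically; the mean absolute time offset is recorded as the pair's
#' time gap. Returns `NULL` when the window holds no reading. A BP reading
#' may contribute to several ECGs whose windows overlap.
#'
#' @param ecg_time ECG start time, seconds.
#' @param bp data.frame with `time`, `sbp`, `dbp` (already validated),
#'   time-sorted.
#' @param cfg a [clean_config()].
#' @return list `mean_sbp`, `mean_dbp`, `n_bp`, `mean_gap_s`, or `NULL`.
#' @export
pair_ecg_bp <- function(ecg_time, bp, cfg = clean_config()) {
  dt <- bp$time - ecg_time
  inw <- abs(dt) <= cfg$window_s
  if (!any(inw)) return(NULL)
  list(mean_sbp = mean(bp$sbp[inw]),
       mean_dbp = mean(bp$dbp[inw]),
       n_bp = sum(inw),
       mean_gap_s = mean(abs(dt[inw])))
}

#' Cap the number of pairs per subject
#'
#' Subjects with more than `max_records_per_subject` pairs have that many
#' selected uniformly at random without replacement (deterministic per
#' `cap_seed`); subjects at or below the cap are untouched. The selection is
#' drawn once per experiment, not per CV fold, so every model sees identical
#' folds.
#'
#' @param samples paired-sample data.frame with `record_id`, `subject_id`.
#' @param cfg a [clean_config()].
#' @return the capped data.frame.
#' @export
cap_records_per_subject <- function(samples, cfg = clean_config()) {
  keep <- unlist(lapply(split(seq_len(nrow(samples)), samples$subject_id),
    function(idx) {
      if (length(idx) <= cfg$max_records_per_subject) return(idx)
      sid <- samples$subject_id[idx[1]]
      with_seed(derive_seed(cfg$cap_seed, "cap", sid),
                sort(sample(idx, cfg$max_records_per_subject)))
    }))
  samples[sort(keep), , drop = FALSE]
}

#' Run the full cleaning and pairing workflow
#'
#' Applies, in order: subject age/sex filtering, record-length
#' standardization (too-short exclusion), rhythm-label filtering, BP validity
#' screening, windowed ECG-BP pairing with averaging, and per-subject
#' capping. Returns the paired-sample table plus a cleaning report whose
#' per-stage counts reconcile exactly with the exclusion reasons.
#'
#' @param study an `ecgbp_study` (or a compatible list of `subjects`,
#'   `records`, `bp_log`).
#' @param cfg a [clean_config()].
#' @return list with `paired` (data.frame: `record_id`, `subject_id`, `sex`,
#'   `age_years`, `mean_sbp`, `mean_dbp`, `n_bp`, `mean_gap_s`,
#'   `rhythm_label`, `is_normal`) and `report` (per-stage in/out counts and
#'   reason histogram).
#' @export
clean_cohort <- function(study, cfg = clean_config()) {
  meta <- do.call(rbind, lapply(study$records, function(r)
    data.frame(record_id = r$record$record_id,
               subject_id = r$record$subject_id,
               start_time = r$record$start_time,
               duration_s = r$record$duration_s,
               rhythm_label = if (is.null(r$record$rhythm_label) ||
                                  is.na(r$record$rhythm_label))
                 NA_character_ else r$record$rhythm_label,
               stringsAsFactors = FALSE)))
  stages <- list()
  reasons <- character(0)
  note <- function(stage, n_in, n_out, reason_tab) {
    stages[[stage]] <<- list(n_in = n_in, n_out = n_out,
                             reasons = as.list(reason_tab))
  }

  # 1. subject filters
  fs_res <- filter_subjects(study$subjects, meta, cfg)
  note("subject_filter", nrow(meta), nrow(fs_res$kept),
       table(fs_res$excluded$reason))
  cur <- fs_res$kept

  # 2. record length
  ok_len <- cur$duration_s >= 30
  note("length_standardization", nrow(cur), sum(ok_len),
       table(rep("too_short", sum(!ok_len))))
  cur <- cur[ok_len, , drop = FALSE]

  # 3. rhythm labels
  ok_lab <- filter_ecg_labels(cur$rhythm_label, cfg)
  note("label_filter", nrow(cur), sum(ok_lab),
       table(ifelse(is.na(cur$rhythm_label[!ok_lab]), "missing_label",
                    "invalid_label")))
  cur <- cur[ok_lab, , drop = FALSE]

  # 4. BP validity (on the BP log, reported separately)
  bp_status <- validate_bp_measurement(study$bp_log$sbp, study$bp_log$dbp, cfg)
  bp_valid <- study$bp_log[bp_status == "accept", , drop = FALSE]
  bp_valid <- bp_valid[order(bp_valid$subject_id, bp_valid$time), , drop = FALSE]
  stages[["bp_validity"]] <- list(n_in = nrow(study$bp_log),
                                  n_out = nrow(bp_valid),
                                  reasons = as.list(table(
                                    bp_status[bp_status != "accept"])))

  # 5. pairing
  bp_by_subj <- split(bp_valid, bp_valid$subject_id)
  paired_rows <- vector("list", nrow(cur))
  pair_reason <- rep(NA_character_, nrow(cur))
  for (i in seq_len(nrow(cur))) {
    bp <- bp_by_subj[[cur$subject_id[i]]]
    pr <- if (is.null(bp)) NULL else pair_ecg_bp(cur$start_time[i], bp, cfg)
    if (is.null(pr)) { pair_reason[i] <- "no_bp_in_window"; next }
    if (pr$mean_dbp >= pr$mean_sbp) {  # averaged pair must stay ordered
      pair_reason[i] <- "mean_dbp_ge_sbp"; next
    }
    paired_rows[[i]] <- data.frame(
      record_id = cur$record_id[i], subject_id = cur$subject_id[i],
      sex = cur$sex[i], age_years = cur$age_years[i],
      mean_sbp = pr$mean_sbp, mean_dbp = pr$mean_dbp, n_bp = pr$n_bp,
      mean_gap_s = pr$mean_gap_s, rhythm_label = cur$rhythm_label[i],
      is_normal = cur$rhythm_label[i] == "sinus rhythm",
      stringsAsFactors = FALSE)
  }
  got <- !vapply(paired_rows, is.null, logical(1))
  paired <- do.call(rbind, paired_rows[got])
  if (is.null(paired)) paired <- data.frame()
  note("pairing", nrow(cur), sum(got), table(pair_reason[!got]))

  # 6. cap
  if (nrow(paired) > 0) {
    capped <- cap_records_per_subject(paired, cfg)
  } else capped <- paired
  note("cap_records_per_subject", nrow(paired), nrow(capped),
       table(rep("over_cap", nrow(paired) - nrow(capped))))

  list(paired = capped,
       report = list(stages = stages,
                     n_records_in = nrow(meta),
                     n_pairs_out = nrow(capped)))
}

#' Write paired samples and the cleaning report
#'
#' @param cleaned result of [clean_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cleaned <- function(cleaned, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cleaned$paired, file.path(dir, "paired_samples.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cleaned$report, file.path(dir, "cleaning_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
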