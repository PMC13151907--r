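## Synthetic cohort generator
##
## Emulates an ambulatory home-monitoring study in which single-lead 30 s ECGs
## and oscillometric cuff BP readings are self-recorded asynchronously: each
## subject contributes a variable number of ECGs and BP readings, the two
## modalities are offset by seconds-to-hours, BP has sex-specific population
## distributions and a subject-level random intercept, and an optional planted
## HR -> BP coupling provides a recoverable signal for positive controls.

#' Default PQRST wave template
#'
#' Each heartbeat is a sum of five Gaussian waves on the RR grid. Centers are
#' offsets from the R peak in seconds; widths are Gaussian SDs in seconds;
#' amplitudes in mV. Chosen for analytic tractability: peak positions, 10%
#' onsets/offsets and areas all have closed forms.
#'
#' @return data.frame with columns `wave`, `amp`, `center_s`, `width_s`.
#' @export
ecg_wave_params <- function() {
  data.frame(
    wave     = c("P", "Q", "R", "S", "T"),
    amp      = c(0.12, -0.15, 1.00, -0.25, 0.35),
    center_s = c(-0.200, -0.035, 0.000, 0.035, 0.300),
    width_s  = c(0.025, 0.010, 0.012, 0.010, 0.050)
  )
}

#' Simulation configuration
#'
#' All knobs of the synthetic study in one validated object. Population BP
#' parameters default to the sex-specific means/SDs of the emulated ambulatory
#' cohort (male SBP 127.1 (16.0), female SBP 123.8 (17.0), male DBP 80.2
#' (10.5), female DBP 78.9 (11.0) mmHg); abnormal-rhythm record fractions
#' default to 14.3% (male) and 12.1% (female).
#'
#' @param n_subjects number of subjects.
#' @param seed root seed; every random stream derives from it.
#' @param sex_fraction_male fraction of male subjects (record-weighted cohorts
#'   in this setting are male-dominated; default 0.81).
#' @param records_per_subject_dist [dist_spec()] for ECG count per subject;
#'   default log-normal with median 6.
#' @param bp_per_record_dist [dist_spec()] for the number of BP readings
#'   anchored near each ECG; default Poisson(1.3).
#' @param gap_dist [dist_spec()] for the signed ECG-to-BP offset in seconds.
#' @param coupling_beta_sbp,coupling_beta_dbp planted HR->BP coupling,
#'   mmHg per bpm of deviation from the subject's baseline HR (default 0:
#'   the null world in which ECG carries no BP information).
#' @param drift_rate short-term BP drift rate, mmHg per minute of elapsed
#'   time between consecutive readings; default 5/3.5 so that BP drifts by
#'   about 5 mmHg RMS over a 3.5 min interval.
#' @param drift_sd_max saturation of the per-step drift SD, mmHg: day-scale
#'   gaps between readings drift by this much rather than growing without
#'   bound (long-term within-subject BP variability).
#' @param drift_tau_min mean-reversion time constant of the drift, minutes:
#'   over gaps much longer than this the drift decays back toward the
#'   subject baseline, so the walk's variance stays stationary over months
#'   of observation. Negligible effect at the 3.5-minute pairing scale.
#' @param measurement_noise_sd cuff measurement noise SD, mmHg.
#' @param ecg_noise_sd additive white ECG noise SD, mV.
#' @param fs ECG sampling frequency, Hz.
#' @param duration_s ECG record length, seconds.
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd named numeric `c(male=, female=)`
#'   population baselines, mmHg.
#' @param hr_mean,hr_between_sd,hr_within_sd population mean baseline HR,
#'   between-subject SD and within-subject (record-to-record) SD, bpm.
#' @param abnormal_rhythm_prob named `c(male=, female=)` probability that a
#'   record is abnormal-rhythm.
#' @param age_min,age_max uniform age range, years.
#' @param rr_cv_normal,rr_cv_abnormal coefficient of variation of RR
#'   intervals for normal and irregular-rhythm records.
#' @param morph_amp_sdlog,morph_width_sdlog log-normal SDs of the per-subject
#'   wave amplitude / width multipliers (subject morphology fingerprint).
#' @param frac_unreadable,frac_missing_label,frac_too_short fractions of
#'   records planted with an `unreadable` label, a missing label, or a
#'   short (<30 s) duration, to exercise the cleaning stages.
#' @param unknown_sex_frac fraction of subjects with unrecorded sex.
#' @param invalid_bp_frac fraction of BP readings planted invalid
#'   (SBP/DBP swapped or out of physiologic range).
#' @param orphan_bp_rate Poisson rate of extra BP readings per subject at
#'   times unrelated to any ECG (window-exclusion fodder).
#' @param study_days length of the simulated observation window.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects,
                       seed = 1L,
                       sex_fraction_male = 0.81,
                       records_per_subject_dist = dist_spec("lognormal",
                         meanlog = log(6), sdlog = 0.8),
                       bp_per_record_dist = dist_spec("poisson", lambda = 1.3),
                       gap_dist = dist_spec("normal", mean = 0, sd = 150),
                       coupling_beta_sbp = 0,
                       coupling_beta_dbp = 0,
                       drift_rate = 5 / 3.5,
                       drift_sd_max = 8,
                       drift_tau_min = 1440,
                       measurement_noise_sd = 5,
                       ecg_noise_sd = 0.05,
                       fs = 300,
                       duration_s = 30,
                       sbp_mean = c(male = 127.1, female = 123.8),
                       sbp_sd   = c(male = 16.0,  female = 17.0),
                       dbp_mean = c(male = 80.2,  female = 78.9),
                       dbp_sd   = c(male = 10.5,  female = 11.0),
                       hr_mean = 72,
                       hr_between_sd = 10,
                       hr_within_sd = 3,
                       abnormal_rhythm_prob = c(male = 0.143, female = 0.121),
                       age_min = 18, age_max = 90,
                       rr_cv_normal = 0.04,
                       rr_cv_abnormal = 0.25,
                       morph_amp_sdlog = 0.10,
                       morph_width_sdlog = 0.05,
                       frac_unreadable = 0.01,
                       frac_missing_label = 0.005,
                       frac_too_short = 0.01,
                       unknown_sex_frac = 0.005,
                       invalid_bp_frac = 0.01,
                       orphan_bp_rate = 2,
                       study_days = 90,
                       wave_params = ecg_wave_params()) {
  if (sex_fraction_male < 0 || sex_fraction_male > 1)
    ecgbp_stop("ecgbp_config_error", "invalid sex_fraction_male: %g",
               sex_fraction_male)
  if (n_subjects < 1) ecgbp_stop("ecgbp_config_error", "n_subjects must be >= 1")
  sds <- c(sbp_sd, dbp_sd, measurement_noise_sd, ecg_noise_sd,
           hr_between_sd, hr_within_sd)
  if (any(sds < 0)) ecgbp_stop("ecgbp_config_error", "all SDs must be >= 0")
  if (fs <= 0 || duration_s <= 0)
    ecgbp_stop("ecgbp_config_error", "fs and duration_s must be positive")
  if (abs(fs * duration_s - round(fs * duration_s)) > 1e-9)
    ecgbp_stop("ecgbp_config_error",
               "fs * duration_s must be a whole number of samples")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Generate a cohort of subject profiles
#'
#' Subject-level baselines are drawn from sex-specific normal distributions;
#' the subject SBP/DBP baseline is the subject random effect that all of the
#' subject's BP readings share. DBP baselines are clamped below SBP - 10 mmHg
#' to preserve the physiologic ordering.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per subject: `subject_id`, `sex`,
#'   `age_years`, `sbp_baseline`, `dbp_baseline`, `hr_baseline`,
#'   `abnormal_rhythm_prob`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  with_seed(derive_seed(config$seed, "cohort"), {
    sex <- ifelse(stats::runif(n) < config$sex_fraction_male, "male", "female")
    unknown <- stats::runif(n) < config$unknown_sex_frac
    age <- stats::runif(n, config$age_min, config$age_max)
    sbp <- stats::rnorm(n, config$sbp_mean[sex], config$sbp_sd[sex])
    dbp <- stats::rnorm(n, config$dbp_mean[sex], config$dbp_sd[sex])
    dbp <- pmin(dbp, sbp - 10)
    hr <- pmin(pmax(stats::rnorm(n, config$hr_mean, config$hr_between_sd), 40), 150)
    out <- data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      sex = ifelse(unknown, "unknown", sex),
      age_years = age,
      sbp_baseline = sbp,
      dbp_baseline = dbp,
      hr_baseline = hr,
      abnormal_rhythm_prob = unname(config$abnormal_rhythm_prob[sex]),
      stringsAsFactors = FALSE
    )
    out
  })
}

# per-subject morphology fingerprint: multiplicative jitters on wave
# amplitudes and widths, deterministic in (config seed, subject id)
subject_morphology <- function(config, subject_id) {
  with_seed(derive_seed(config$seed, "morph", subject_id), {
    list(amp_f = stats::rlnorm(5, 0, config$morph_amp_sdlog),
         width_f = stats::rlnorm(5, 0, config$morph_width_sdlog))
  })
}

valid_rhythm_labels <- function() {
  c("sinus rhythm", "atrial fibrillation", "bradycardia", "tachycardia",
    "too short", "unclassified")
}

#' Synthesize one ECG record with ground truth
#'
#' Builds a 30 s (by default) single-lead ECG as a sum of five Gaussian waves
#' (P, Q, R, S, T) per beat on an RR grid derived from the record's true heart
#' rate plus HRV jitter, plus additive white noise. Ground truth (true R-peak
#' sample indices, per-beat wave centers/widths/amplitudes and analytic 10%
#' onsets/offsets, true HR) is returned alongside for oracle testing.
#' Deterministic in `(profile, config, at)`.
#'
#' @param profile one-row subject data.frame (a [generate_cohort()] row).
#' @param config a [sim_config()].
#' @param at record start time, seconds from the study origin.
#' @param record_id optional id; derived from subject and time if omitted.
#' @param hr_true optional override of the record's true HR, bpm.
#' @param rhythm_label optional override of the rhythm label.
#' @param rr_cv optional override of the RR coefficient of variation.
#' @param duration_s optional override of the record duration.
#' @return list with elements `record` (class `ecg_record`: `record_id`,
#'   `subject_id`, `start_time`, `fs`, `samples`, `rhythm_label`,
#'   `duration_s`) and `ground_truth` (class `ecg_ground_truth`: `r_idx`,
#'   `fiducials_true`, `hr_true`).
#' @export
synth_ecg_record <- function(profile, config, at, record_id = NULL,
                             hr_true = NULL, rhythm_label = NULL,
                             rr_cv = NULL, duration_s = NULL) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs
  dur <- if (is.null(duration_s)) config$duration_s else duration_s
  if (fs <= 0 || dur <= 0)
    ecgbp_stop("ecgbp_config_error", "fs and duration must be positive")
  n_samp <- round(fs * dur)
  morph <- subject_morphology(config, profile$subject_id)
  wp <- config$wave_params
  wp$amp <- wp$amp * morph$amp_f
  wp$width_s <- wp$width_s * morph$width_f

  with_seed(derive_seed(config$seed, "ecg", profile$subject_id, round(at * 1000)), {
    abnormal <- stats::runif(1) < profile$abnormal_rhythm_prob
    if (is.null(rhythm_label)) {
      if (abnormal) {
        rhythm_label <- sample(c("atrial fibrillation", "bradycardia",
                                 "tachycardia", "unclassified"),
                               1, prob = c(0.55, 0.15, 0.15, 0.15))
      } else rhythm_label <- "sinus rhythm"
    }
    if (is.null(hr_true)) {
      hr_true <- switch(rhythm_label,
        bradycardia = stats::runif(1, 32, 48),
        tachycardia = stats::runif(1, 115, 160),
        profile$hr_baseline + stats::rnorm(1, 0, config$hr_within_sd))
      hr_true <- min(max(hr_true, 25), 240)
    }
    if (hr_true <= 20 || hr_true >= 250)
      ecgbp_stop("ecgbp_config_error", "hr_true outside (20, 250): %g", hr_true)
    if (is.null(rr_cv)) {
      rr_cv <- switch(rhythm_label,
        `atrial fibrillation` = config$rr_cv_abnormal,
        unclassified = 0.15,
        config$rr_cv_normal)
    }

    rr_mean <- 60 / hr_true
    # rate adaptation: P and T offsets (and widths) shrink with sqrt(RR),
    # mimicking PR/QT shortening at higher rates and keeping waves of
    # neighboring beats separated
    rate_scale <- min(max(sqrt(rr_mean), 0.6), 1.15)
    pt <- wp$wave %in% c("P", "T")
    wp$center_s[pt] <- wp$center_s[pt] * rate_scale
    wp$width_s[pt] <- wp$width_s[pt] * rate_scale
    n_beats_max <- ceiling(dur / rr_mean) + 3
    rr <- rr_mean * pmax(0.4, 1 + rr_cv * stats::rnorm(n_beats_max))
    t0 <- stats::runif(1, 0.2, 0.8) * rr[1]
    r_times <- cumsum(c(t0, rr))[seq_len(n_beats_max)]
    r_times <- r_times[r_times < dur - 0.03]
    n_beats <- length(r_times)

    # noiseless waveform: per-beat Gaussians evaluated on a local window;
    # ground-truth fiducials stored as beats-by-waves matrices
    clean <- numeric(n_samp)
    t_grid <- (seq_len(n_samp) - 1) / fs
    k10 <- sqrt(2 * log(10))  # 10% points of a Gaussian at center +/- k10*sigma
    mkm <- function() matrix(NA_real_, n_beats, 5,
                             dimnames = list(NULL, wp$wave))
    gt_center <- mkm(); gt_onset <- mkm(); gt_offset <- mkm(); gt_amp <- mkm()
    for (b in seq_len(n_beats)) {
      centers <- r_times[b] + wp$center_s
      for (w in seq_len(5)) {
        lo <- max(1L, floor((centers[w] - 4 * wp$width_s[w]) * fs) + 1L)
        hi <- min(n_samp, ceiling((centers[w] + 4 * wp$width_s[w]) * fs) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        clean[idx] <- clean[idx] + wp$amp[w] *
          exp(-0.5 * ((t_grid[idx] - centers[w]) / wp$width_s[w])^2)
      }
      gt_center[b, ] <- round(centers * fs) + 1
      gt_onset[b, ] <- round((centers - k10 * wp$width_s) * fs) + 1
      gt_offset[b, ] <- round((centers + k10 * wp$width_s) * fs) + 1
      gt_amp[b, ] <- wp$amp
    }
    fid <- list(center_idx = gt_center, onset_idx = gt_onset,
                offset_idx = gt_offset, amp = gt_amp, width_s = wp$width_s)
    # true R index = local maximum of the noiseless waveform near each R time
    r_idx <- vapply(r_times, function(tt) {
      c0 <- round(tt * fs) + 1L
      win <- max(1L, c0 - 3L):min(n_samp, c0 + 3L)
      win[which.max(clean[win])]
    }, integer(1))

    samples <- clean + stats::rnorm(n_samp, 0, config$ecg_noise_sd)
    if (is.null(record_id))
      record_id <- sprintf("%s_R%09d", profile$subject_id, round(at))
    record <- structure(list(
      record_id = record_id, subject_id = profile$subject_id,
      start_time = at, fs = fs, samples = samples,
      rhythm_label = rhythm_label, duration_s = dur
    ), class = "ecg_record")
    gt <- structure(list(record_id = record_id, r_idx = r_idx,
                         fiducials_true = fid, hr_true = hr_true),
                    class = "ecg_ground_truth")
    list(record = record, ground_truth = gt)
  })
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> subject %s, %.0f s @ %g Hz, label '%s'\n",
              x$record_id, x$subject_id, x$duration_s, x$fs, x$rhythm_label))
  invisible(x)
}

#' Synthesize a BP series for one subject
#'
#' BP at time t is the subject baseline plus a bounded short-term drift, plus
#' the planted HR coupling term, plus iid cuff measurement noise:
#' `sbp(t) = sbp_baseline + drift(t) + beta_sbp * (hr_at(t) - hr_baseline) +
#' noise`. The drift is a random walk over the requested time grid whose
#' increment between consecutive times dt apart has SD `drift_rate * dt`
#' (minutes) saturating at `drift_sd_max`, reflected at +/- 3 population
#' baseline SDs so BP stays physiological. DBP shares the walk scaled by
#' 0.65 with noise scaled by 0.7.
#'
#' @param profile one-row subject data.frame.
#' @param times sorted measurement times, seconds.
#' @param config a [sim_config()].
#' @param hr_at function mapping time (s) to the subject's HR (bpm) at that
#'   moment; defaults to the constant baseline HR.
#' @return data.frame `subject_id`, `time`, `sbp`, `dbp`.
#' @export
synth_bp_series <- function(profile, times, config, hr_at = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.unsorted(times)) ecgbp_stop("ecgbp_data_error", "times must be sorted")
  n <- length(times)
  if (n == 0)
    return(data.frame(subject_id = character(), time = numeric(),
                      sbp = numeric(), dbp = numeric()))
  if (is.null(hr_at)) hr_at <- function(t) rep(profile$hr_baseline, length(t))
  sexkey <- if (profile$sex %in% c("male", "female")) profile$sex else "male"
  bound <- 3 * unname(config$sbp_sd[sexkey])
  drift <- numeric(n)
  if (n > 1) {
    dt_min <- diff(times) / 60
    steps <- stats::rnorm(n - 1, 0, pmin(config$drift_rate * dt_min,
                                         config$drift_sd_max))
    lambda <- exp(-dt_min / config$drift_tau_min)
    d <- 0
    for (i in seq_len(n - 1)) {
      d <- lambda[i] * d + steps[i]
      # reflect into [-bound, bound]
      while (abs(d) > bound) d <- sign(d) * (2 * bound - abs(d))
      drift[i + 1] <- d
    }
  }
  hr_dev <- hr_at(times) - profile$hr_baseline
  sbp <- profile$sbp_baseline + drift +
    config$coupling_beta_sbp * hr_dev +
    stats::rnorm(n, 0, config$measurement_noise_sd)
  dbp <- profile$dbp_baseline + 0.65 * drift +
    config$coupling_beta_dbp * hr_dev +
    stats::rnorm(n, 0, 0.7 * config$measurement_noise_sd)
  data.frame(subject_id = profile$subject_id, time = times, sbp = sbp, dbp = dbp)
}

#' Simulate a full asynchronous ECG + BP study
#'
#' End-to-end dataset generator: draws the cohort, per-subject ECG record
#' times (spaced at least 30 s apart over the study window), synthesizes each
#' ECG with ground truth, anchors a configurable number of BP readings around
#' each ECG via `gap_dist` plus independent orphan readings, and generates the
#' BP series with drift, coupling and noise. A configurable fraction of BP
#' rows is planted invalid (swapped SBP/DBP or out-of-range values) and a
#' fraction of ECGs carries `unreadable`/missing labels or short durations,
#' so the downstream cleaning stages have real work to do.
#'
#' @param config a [sim_config()].
#' @return object of class `ecgbp_study`: list with `subjects` (data.frame),
#'   `records` (list of `list(record, ground_truth)`), `bp_log` (data.frame).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  subjects <- generate_cohort(config)
  horizon <- config$study_days * 86400
  records <- list()
  bp_rows <- list()

  for (i in seq_len(nrow(subjects))) {
    prof <- subjects[i, ]
    sid <- prof$subject_id
    with_seed(derive_seed(config$seed, "schedule", sid), {
      n_rec <- max(1L, round(draw_dist(config$records_per_subject_dist, 1)))
      ecg_times <- sort(stats::runif(n_rec, 0, horizon))
      if (n_rec > 1) for (k in 2:n_rec)
        ecg_times[k] <- max(ecg_times[k], ecg_times[k - 1] + 30)
      short <- stats::runif(n_rec) < config$frac_too_short
      durs <- ifelse(short, round(stats::runif(n_rec, 10, 25)), config$duration_s)
      label_u <- stats::runif(n_rec)
      n_bp_each <- draw_dist(config$bp_per_record_dist, n_rec)
      gaps <- lapply(n_bp_each, function(k) draw_dist(config$gap_dist, k))
      n_orphan <- stats::rpois(1, config$orphan_bp_rate)
      orphan_times <- stats::runif(n_orphan, 0, horizon)
    })

    recs <- vector("list", n_rec)
    for (k in seq_len(n_rec)) {
      lab <- if (short[k]) "too short"
        else if (label_u[k] < config$frac_unreadable) "unreadable"
        else if (label_u[k] < config$frac_unreadable + config$frac_missing_label) NA_character_
        else NULL
      recs[[k]] <- synth_ecg_record(prof, config, at = ecg_times[k],
                                    rhythm_label = lab, duration_s = durs[k])
    }
    records <- c(records, recs)

    hr_by_rec <- vapply(recs, function(r) r$ground_truth$hr_true, numeric(1))
    hr_at <- function(t) {
      vapply(t, function(tt) {
        j <- which.min(abs(ecg_times - tt))
        if (abs(ecg_times[j] - tt) <= 600) hr_by_rec[j] else prof$hr_baseline
      }, numeric(1))
    }
    bp_times <- sort(c(unlist(Map(function(t0, g) t0 + g, ecg_times, gaps)),
                       orphan_times))
    bp_times <- bp_times[bp_times >= 0]
    bp <- with_seed(derive_seed(config$seed, "bp", sid),
                    synth_bp_series(prof, bp_times, config, hr_at))
    if (nrow(bp) > 0) {
      bad <- with_seed(derive_seed(config$seed, "bpinv", sid),
                       stats::runif(nrow(bp)) < config$invalid_bp_frac)
      if (any(bad)) {
        mode3 <- with_seed(derive_seed(config$seed, "bpinv2", sid),
                           sample(3, sum(bad), replace = TRUE))
        j <- which(bad)
        swap <- j[mode3 == 1]                       # dbp >= sbp
        tmp <- bp$sbp[swap]; bp$sbp[swap] <- bp$dbp[swap]; bp$dbp[swap] <- tmp
        bp$sbp[j[mode3 == 2]] <- 15                 # sbp below valid range
        bp$dbp[j[mode3 == 3]] <- 210                # dbp above valid range
      }
    }
    bp_rows[[i]] <- bp
  }

  structure(list(subjects = subjects,
                 records = records,
                 bp_log = do.call(rbind, bp_rows)),
            class = "ecgbp_study")
}

#' Read a study back from its on-disk representation
#'
#' Counterpart of [write_study()]. Waveforms are loaded only when the
#' `signals/` directory exists; the cleaning/pairing stages need metadata
#' only.
#'
#' @param dir directory written by [write_study()].
#' @return an `ecgbp_study` (records carry `samples = NULL` when waveforms
#'   were not written).
#' @export
read_study <- function(dir) {
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  bp <- utils::read.csv(file.path(dir, "bp_log.csv"), stringsAsFactors = FALSE)
  bp$time <- parse_iso8601(bp$iso8601_time)
  man <- utils::read.csv(file.path(dir, "records.csv"),
                         stringsAsFactors = FALSE)
  sigdir <- file.path(dir, "signals")
  records <- lapply(seq_len(nrow(man)), function(i) {
    samples <- NULL
    f <- file.path(sigdir, paste0(man$record_id[i], ".csv"))
    if (file.exists(f)) samples <- utils::read.csv(f)$mv
    list(record = structure(list(
      record_id = man$record_id[i], subject_id = man$subject_id[i],
      start_time = parse_iso8601(man$iso8601_start[i]), fs = man$fs[i],
      samples = samples,
      rhythm_label = if (is.na(man$label[i]) || man$label[i] == "")
        NA_character_ else man$label[i],
      duration_s = man$duration_s[i]), class = "ecg_record"))
  })
  structure(list(subjects = subjects, records = records,
                 bp_log = bp[, c("subject_id", "time", "sbp", "dbp")]),
            class = "ecgbp_study")
}

#' @export
print.ecgbp_study <- function(x, ...) {
  cat(sprintf("<ecgbp_study> %d subjects, %d ECG records, %d BP readings\n",
              nrow(x$subjects), length(x$records), nrow(x$bp_log)))
  invisible(x)
}

#' Write a simulated study to disk in plain-text formats
#'
#' Writes `subjects.csv`, `bp_log.csv` (ISO-8601 times), a `records.csv`
#' manifest, optional per-record waveform CSVs (`time_s`, `mv`) and
#' `ground_truth.json`.
#'
#' @param study an `ecgbp_study`.
#' @param dir output directory (created if needed).
#' @param write_signals also write one waveform CSV per record?
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, write_signals = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  bp <- study$bp_log
  bp$iso8601_time <- iso8601(bp$time)
  utils::write.csv(bp[, c("subject_id", "iso8601_time", "sbp", "dbp")],
                   file.path(dir, "bp_log.csv"), row.names = FALSE)
  man <- do.call(rbind, lapply(study$records, function(r)
    data.frame(record_id = r$record$record_id,
               subject_id = r$record$subject_id,
               iso8601_start = iso8601(r$record$start_time),
               fs = r$record$fs,
               duration_s = r$record$duration_s,
               label = r$record$rhythm_label)))
  utils::write.csv(man, file.path(dir, "records.csv"), row.names = FALSE)
  gt <- lapply(study$records, function(r)
    list(record_id = r$ground_truth$record_id,
         r_idx = r$ground_truth$r_idx,
         hr_true = r$ground_truth$hr_true))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (write_signals) {
    sigdir <- file.path(dir, "signals")
    dir.create(sigdir, showWarnings = FALSE)
    for (r in study$records) {
      rec <- r$record
      utils::write.csv(
        data.frame(time_s = (seq_along(rec$samples) - 1) / rec$fs,
                   mv = rec$samples),
        file.path(sigdir, paste0(rec$record_id, ".csv")), row.names = FALSE)
    }
  }
  invisible(dir)
}
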