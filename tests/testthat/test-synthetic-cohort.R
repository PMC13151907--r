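# Synthetic cohort generator: distributional recovery, seeded determinism,
# waveform/ground-truth consistency, BP series laws.

test_that("cohort baselines recover the configured sex-specific distributions", {
  cfg <- quiet_sim_config(n_subjects = 1000, seed = 101)
  coh <- generate_cohort(cfg)
  male <- coh[coh$sex == "male", ]
  # 3*SE envelope: 16 / sqrt(n_male) * 3 < 1.6
  expect_lt(abs(mean(male$sbp_baseline) - 127.1), 3 * 16 / sqrt(nrow(male)))
  expect_lt(abs(sd(male$sbp_baseline) - 16.0), 2.5)
  female <- coh[coh$sex == "female", ]
  expect_lt(abs(mean(female$sbp_baseline) - 123.8), 3 * 17 / sqrt(nrow(female)))
  expect_lt(abs(mean(female$dbp_baseline) - 78.9), 3 * 11 / sqrt(nrow(female)))
  expect_lt(abs(mean(coh$sex == "male") - 0.81), 3 * sqrt(0.81 * 0.19 / 1000))
  expect_true(all(coh$dbp_baseline < coh$sbp_baseline))
  expect_true(all(coh$hr_baseline > 20 & coh$hr_baseline < 250))
})

test_that("cohort generation is deterministic and degenerate SDs collapse", {
  cfg <- quiet_sim_config(n_subjects = 5, seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg0 <- quiet_sim_config(n_subjects = 50, seed = 7,
                           sbp_sd = c(male = 0, female = 0))
  coh <- generate_cohort(cfg0)
  expect_true(all(coh$sbp_baseline[coh$sex == "male"] == 127.1))
  expect_true(all(coh$sbp_baseline[coh$sex == "female"] == 123.8))
  expect_error(sim_config(10, sex_fraction_male = 1.2), "sex_fraction")
  expect_error(sim_config(10, fs = 300, duration_s = 30.0001), "whole number")
})

test_that("ECG synthesis: beat count, template amplitude, determinism", {
  cfg <- quiet_sim_config(seed = 3, ecg_noise_sd = 0,
                          morph_amp_sdlog = 0, morph_width_sdlog = 0)
  coh <- generate_cohort(cfg)
  r <- synth_ecg_record(coh[1, ], cfg, at = 50, hr_true = 60,
                        rhythm_label = "sinus rhythm")
  expect_equal(length(r$record$samples), 9000)
  expect_true(abs(length(r$ground_truth$r_idx) - 30) <= 1)
  # each true R is a local max of the noiseless waveform, at R amplitude ~1;
  # tolerance from direct evaluation of the template: Q/S Gaussian overlap at
  # the R center (~7e-4) plus up to half a sample of grid discretization on
  # the R Gaussian (1 - exp(-0.5 * (0.5/3.6)^2) ~ 1e-2)
  x <- r$record$samples
  for (ri in r$ground_truth$r_idx) {
    expect_equal(which.max(x[(ri - 3):(ri + 3)]), 4)
    expect_lt(abs(x[ri] - 1.0), 0.02)
  }
  r2 <- synth_ecg_record(coh[1, ], cfg, at = 50, hr_true = 60,
                         rhythm_label = "sinus rhythm")
  expect_identical(r$record$samples, r2$record$samples)
  expect_error(synth_ecg_record(coh[1, ], cfg, at = 0, hr_true = 300),
               "hr_true")
})

test_that("abnormal-rhythm records have irregular RR and abnormal labels", {
  cfg <- quiet_sim_config(seed = 5, ecg_noise_sd = 0)
  coh <- generate_cohort(cfg)
  r <- synth_ecg_record(coh[1, ], cfg, at = 10,
                        rhythm_label = "atrial fibrillation")
  rr <- diff(r$ground_truth$r_idx) / 300
  expect_gt(sd(rr) / mean(rr), 0.1)
  expect_equal(r$record$rhythm_label, "atrial fibrillation")
})

test_that("BP series follows the stated composition law", {
  cfg <- quiet_sim_config(seed = 9, coupling_beta_sbp = 0, drift_rate = 0,
                          measurement_noise_sd = 0)
  prof <- generate_cohort(cfg)[1, ]
  bp <- synth_bp_series(prof, c(0, 100, 5000), cfg)
  expect_equal(bp$sbp, rep(prof$sbp_baseline, 3))
  expect_equal(bp$dbp, rep(prof$dbp_baseline, 3))

  cfg2 <- quiet_sim_config(seed = 9, coupling_beta_sbp = 0.4, drift_rate = 0,
                           measurement_noise_sd = 0)
  bp2 <- synth_bp_series(prof, 0, cfg2,
                         hr_at = function(t) rep(prof$hr_baseline + 20,
                                                 length(t)))
  expect_equal(bp2$sbp, prof$sbp_baseline + 8.0)

  expect_error(synth_bp_series(prof, c(10, 5), cfg), "sorted")
})

test_that("drift RMS over 3.5 minutes matches the configured rate", {
  cfg <- quiet_sim_config(seed = 13, drift_rate = 5 / 3.5,
                          measurement_noise_sd = 0)
  prof <- generate_cohort(cfg)[1, ]
  set.seed(42)
  d <- vapply(1:8000, function(i) {
    bp <- synth_bp_series(prof, c(0, 210), cfg)
    bp$sbp[2] - bp$sbp[1]
  }, numeric(1))
  expect_lt(abs(sqrt(mean(d^2)) - 5) / 5, 0.05)
})

test_that("simulate_study honors count and gap distributions", {
  cfg <- quiet_sim_config(
    n_subjects = 12, seed = 21,
    records_per_subject_dist = dist_spec("fixed", value = 1),
    bp_per_record_dist = dist_spec("fixed", value = 1),
    gap_dist = dist_spec("fixed", value = 60),
    orphan_bp_rate = 0)
  st <- simulate_study(cfg)
  expect_equal(length(st$records), 12)
  starts <- vapply(st$records, function(r) r$record$start_time, numeric(1))
  expect_equal(sort(st$bp_log$time), sort(starts + 60))
})

test_that("abnormal-label mix matches the configured sex-specific fractions", {
  cfg <- quiet_sim_config(
    n_subjects = 150, seed = 31,
    records_per_subject_dist = dist_spec("fixed", value = 4),
    bp_per_record_dist = dist_spec("fixed", value = 0), orphan_bp_rate = 0)
  st <- simulate_study(cfg)
  labs <- vapply(st$records, function(r) r$record$rhythm_label, character(1))
  sids <- vapply(st$records, function(r) r$record$subject_id, character(1))
  sex <- st$subjects$sex[match(sids, st$subjects$subject_id)]
  abn <- labs != "sinus rhythm"
  n_m <- sum(sex == "male")
  p_m <- mean(abn[sex == "male"])
  expect_lt(abs(p_m - 0.143), 3 * sqrt(0.143 * 0.857 / n_m))
})

test_that("a study round-trips through its plain-text file formats", {
  cfg <- quiet_sim_config(n_subjects = 3, seed = 61,
                          records_per_subject_dist = dist_spec("fixed",
                                                               value = 2))
  st <- simulate_study(cfg)
  dir <- file.path(tempdir(), "study_io")
  write_study(st, dir, write_signals = TRUE)
  back <- read_study(dir)
  expect_equal(back$subjects$subject_id, st$subjects$subject_id)
  expect_equal(nrow(back$bp_log), nrow(st$bp_log))
  expect_equal(back$bp_log$sbp, st$bp_log$sbp, tolerance = 1e-6)
  # timestamps survive the ISO-8601 round trip to 1 s resolution
  expect_lt(max(abs(sort(back$bp_log$time) - sort(st$bp_log$time))), 1)
  r1 <- back$records[[1]]$record
  expect_equal(r1$record_id, st$records[[1]]$record$record_id)
  expect_equal(r1$samples, st$records[[1]]$record$samples, tolerance = 1e-6)
  # cleaning runs identically on the re-read study
  expect_equal(clean_cohort(back)$report$stages$pairing$n_out,
               clean_cohort(st)$report$stages$pairing$n_out)
})

test_that("full study simulation is deterministic for a fixed seed", {
  cfg <- quiet_sim_config(n_subjects = 3, seed = 77,
                          records_per_subject_dist = dist_spec("fixed",
                                                               value = 2))
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$subjects, s2$subjects)
  expect_identical(s1$bp_log, s2$bp_log)
  expect_identical(s1$records[[3]]$record$samples,
                   s2$records[[3]]$record$samples)
})
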