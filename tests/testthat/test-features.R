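# ECG feature extractor: manifest integrity, detector recovery, template
# robustness, closed-form oracles for HRV / QTc / areas / slopes / Hjorth /
# SVD, and the scale-equivariance audit.

test_that("the feature manifest is the fixed 128-entry normative artifact", {
  man <- feature_manifest()
  expect_equal(nrow(man), 128)
  expect_false(anyDuplicated(man$name) > 0)
  expect_true(all(man$group %in% c("snr", "hrv", "interval", "amplitude",
                                   "slope", "hjorth", "svd")))
  expect_equal(sum(man$group == "svd"), 45)
  expect_equal(sum(man$group == "hrv"), 6)
  expect_equal(sum(man$group == "hjorth"), 2)
  expect_equal(nrow(feature_manifest(include_meta = TRUE)), 130)
  # the shipped JSON is the same manifest
  shipped <- read_manifest(system.file("extdata", "feature_manifest_v1.json",
                                       package = "ecgbp"))
  expect_equal(shipped$name, man$name)
  expect_equal(shipped$summary_stat, man$summary_stat)
})

test_that("R-peak detector recovers ground truth exactly on clean records", {
  cfg <- quiet_sim_config(n_subjects = 4, seed = 17, ecg_noise_sd = 0)
  coh <- generate_cohort(cfg)
  for (hr in c(50, 72, 95)) {
    r <- synth_ecg_record(coh[1, ], cfg, at = 100 * hr, hr_true = hr,
                          rhythm_label = "sinus rhythm")
    rp <- detect_r_peaks(r$record)
    expect_equal(length(rp$r_idx), length(r$ground_truth$r_idx))
    expect_lte(max(abs(rp$r_idx - r$ground_truth$r_idx)), 3)
  }
  expect_error(detect_r_peaks(make_record(rep(0, 9000))),
               class = "ecgbp_insufficient_beats")
})

test_that("beat segmentation drops edge beats and applies the odd-window rule", {
  # RR = 1 s at 300 Hz: median window is 301 samples
  expect_equal(ecgbp:::odd_window(300), 301L)
  expect_equal(ecgbp:::odd_window(301), 301L)
  expect_equal(ecgbp:::odd_window(299.5), 299L)

  x <- rep(0, 9000)
  r_idx <- seq(150, 8850, by = 300)
  x[r_idx] <- 1
  rec <- make_record(x)
  rp <- detect_r_peaks(rec)
  b <- segment_beats(rec, rp)
  expect_equal(b$window_samples, 301L)
  # first peak at 150 cannot host a 301 window
  expect_equal(nrow(b$beats), length(rp$r_idx) - 1)
  expect_error(segment_beats(rec, rp, window_samples = 4), "odd")
})

test_that("robust template beats resist a gross artifact beat", {
  set.seed(8)
  template <- sin(seq(0, pi, length.out = 101))
  clean <- matrix(rep(template, 9), nrow = 9, byrow = TRUE)
  identical_res <- robust_average_beats(clean)
  expect_equal(identical_res$rwa, template)
  expect_equal(identical_res$rbm, template)

  artifact <- template + 25
  beats <- rbind(clean, artifact)
  res <- robust_average_beats(beats)
  expect_equal(res$rbm, template)  # pointwise median ignores the outlier
  plain <- colMeans(beats)
  expect_lt(sum((res$rwa - template)^2), sum((plain - template)^2))

  two <- rbind(template, template + 1)
  res2 <- robust_average_beats(two)
  expect_equal(res2$rbm, template + 0.5)  # median of two = mean of two
})

test_that("beat SNR matches the white-noise oracle and caps cleanly", {
  template <- sin(seq(0, 2 * pi, length.out = 201))
  clean <- matrix(rep(template, 10), nrow = 10, byrow = TRUE)
  snr0 <- beat_snr(clean, template, template)
  expect_true(all(snr0$snr_rwa == 100))
  expect_true(all(snr0$snr_rbm == 100))

  set.seed(12)
  sigma <- 0.1
  noisy <- clean[rep(1, 400), ] + matrix(rnorm(400 * 201, 0, sigma), 400)
  tpl <- robust_average_beats(noisy)
  snr <- beat_snr(noisy, tpl$rwa, tpl$rbm)
  expected_db <- 10 * log10(mean(template^2) / sigma^2)
  expect_lt(abs(median(snr$snr_rwa) - expected_db), 1)
  expect_lt(abs(median(snr$snr_rbm) - expected_db), 1)

  zero <- rbind(rep(0, 5), rep(1, 5))
  expect_true(is.na(beat_snr(zero, rep(0.5, 5), rep(0.5, 5))$snr_rwa[1]))
})

test_that("HR/HRV metrics have their closed forms", {
  mk_rp <- function(rr_ms) {
    idx <- cumsum(c(1, round(rr_ms / 1000 * 300)))
    structure(list(record_id = "x", r_idx = idx, rr_s = diff(idx) / 300,
                   fs = 300), class = "rpeak_set")
  }
  m <- hr_hrv_metrics(mk_rp(rep(1000, 30)))
  expect_equal(unlist(m), c(hr_mean = 60, hr_median = 60, hr_p5 = 60,
                            hr_p95 = 60, sdnn = 0, rmssd = 0))
  rr <- rep(c(800, 1200), 50)
  m2 <- hr_hrv_metrics(mk_rp(rr))
  expect_equal(m2$rmssd, 400)
  expect_equal(m2$sdnn, sd(rr), tolerance = 1e-12)
  expect_equal(m2$hr_mean, mean(c(75, 50)))
  # two peaks = one RR: insufficient
  m3 <- hr_hrv_metrics(mk_rp(1000))
  expect_true(all(is.na(unlist(m3))))
})

test_that("fiducial detection recovers known wave positions and flags absences", {
  cfg <- quiet_sim_config(seed = 23, ecg_noise_sd = 0,
                          morph_amp_sdlog = 0, morph_width_sdlog = 0)
  coh <- generate_cohort(cfg)
  r <- synth_ecg_record(coh[1, ], cfg, at = 5, hr_true = 60,
                        rhythm_label = "sinus rhythm")
  rp <- detect_r_peaks(r$record)
  fid <- detect_fiducials(r$record, rp)
  gtf <- r$ground_truth$fiducials_true
  nb <- length(rp$r_idx)
  int <- 2:(nb - 1)
  for (w in c("P", "Q", "S", "T")) {
    expect_lte(max(abs(fid$peak[int, w] - gtf$center_idx[int, w])), 3)
  }
  # a record built without a P wave flags P absent
  wp <- ecg_wave_params(); wp$amp[wp$wave == "P"] <- 0
  cfg_nop <- quiet_sim_config(seed = 23, ecg_noise_sd = 0,
                              morph_amp_sdlog = 0, morph_width_sdlog = 0,
                              wave_params = wp)
  r2 <- synth_ecg_record(coh[1, ], cfg_nop, at = 5, hr_true = 60,
                         rhythm_label = "sinus rhythm")
  rp2 <- detect_r_peaks(r2$record)
  fid2 <- detect_fiducials(r2$record, rp2)
  expect_true(all(!fid2$present[int, "P"]))

  # inverted QRS: R amplitude negative, Q/S resolve as positive extrema
  wpi <- ecg_wave_params(); wpi$amp <- -wpi$amp
  cfg_inv <- quiet_sim_config(seed = 23, ecg_noise_sd = 0,
                              morph_amp_sdlog = 0, morph_width_sdlog = 0,
                              wave_params = wpi)
  r3 <- synth_ecg_record(coh[1, ], cfg_inv, at = 5, hr_true = 60,
                         rhythm_label = "sinus rhythm")
  rp3 <- detect_r_peaks(r3$record)
  fid3 <- detect_fiducials(r3$record, rp3)
  expect_true(all(fid3$amp[int, "R"] < 0))
  expect_true(all(fid3$amp[int, "Q"] > 0, na.rm = TRUE))
  expect_true(all(fid3$amp[int, "S"] > 0, na.rm = TRUE))
})

test_that("interval features match ground truth within two samples", {
  cfg <- quiet_sim_config(seed = 29, ecg_noise_sd = 0,
                          morph_amp_sdlog = 0, morph_width_sdlog = 0)
  coh <- generate_cohort(cfg)
  for (hr in c(55, 70, 85)) {
    r <- synth_ecg_record(coh[1, ], cfg, at = hr, hr_true = hr,
                          rhythm_label = "sinus rhythm")
    rp <- detect_r_peaks(r$record)
    fid <- detect_fiducials(r$record, rp)
    iv <- interval_features(fid, rp, r$record)
    gtf <- r$ground_truth$fiducials_true
    fs <- r$record$fs
    int <- 2:(nrow(iv) - 1)
    gt_ms <- function(a, wa, b, wb) (gtf[[a]][int, wa] - gtf[[b]][int, wb]) / fs * 1000
    tol <- 2 / fs * 1000 + 1e-9  # two samples, plus float slack
    expect_lte(max(abs(iv$qrs_dur[int] - gt_ms("offset_idx", "S", "onset_idx", "Q"))),
               tol)
    expect_lte(max(abs(iv$qt[int] - gt_ms("offset_idx", "T", "onset_idx", "Q"))),
               tol)
    expect_lte(max(abs(iv$pr_int[int] - gt_ms("onset_idx", "Q", "onset_idx", "P"))),
               tol)
  }
})

test_that("QTc corrections have their closed forms", {
  # hand-built fiducials: QT = 400 ms, varying RR
  fs <- 1000
  peak <- wave_matrix(Q = 100, R = 150, S = 200, T = 450, nb = 1)
  onset <- wave_matrix(Q = 80, R = 140, S = 190, T = 400, nb = 1)
  offset <- wave_matrix(Q = 120, R = 160, S = 230, T = 480, nb = 1)
  amp <- wave_matrix(Q = -0.1, R = 1, S = -0.2, T = 0.3, nb = 1)
  fid <- make_fiducials(peak, onset, offset, amp, fs = fs)
  rec <- make_record(rep(0, 2000), fs = fs)
  rp_1s <- structure(list(r_idx = c(150, 1150), rr_s = 1, fs = fs),
                     class = "rpeak_set")
  iv <- interval_features(fid, rp_1s, rec)
  expect_equal(iv$qt, 400)
  expect_equal(iv$qtc_b, 400)
  expect_equal(iv$qtc_f, 400)

  rp_640 <- structure(list(r_idx = c(150, 790), rr_s = 0.64, fs = fs),
                      class = "rpeak_set")
  iv2 <- interval_features(fid, rp_640, rec)
  expect_equal(iv2$qtc_b, 400 / sqrt(0.64))  # = 500
  expect_equal(iv2$qtc_b, 500)
  expect_equal(iv2$qtc_f, 400 / 0.64^(1 / 3))
})

test_that("areas match the Gaussian integral and ratios guard division", {
  fs <- 300
  sigma_samp <- 15
  center <- 500
  x <- 0.35 * exp(-0.5 * ((seq_len(1000) - center) / sigma_samp)^2)
  rec <- make_record(x, fs = fs)
  peak <- wave_matrix(R = 100, T = center, nb = 1)
  onset <- wave_matrix(R = 95, T = center - 3 * sigma_samp, nb = 1)
  offset <- wave_matrix(R = 105, T = center + 3 * sigma_samp, nb = 1)
  amp <- wave_matrix(R = 1.0, T = 0.35, nb = 1)
  fid <- make_fiducials(peak, onset, offset, amp, fs = fs)
  aa <- amplitude_area_features(rec, fid)
  expect_lt(abs(aa$area_t - 0.35 * sigma_samp * sqrt(2 * pi)) /
              (0.35 * sigma_samp * sqrt(2 * pi)), 0.02)
  # R amp 1.0, T amp 0.4 -> ratio 2.5
  amp2 <- wave_matrix(R = 1.0, T = 0.4, Q = 0, nb = 1)
  fid2 <- make_fiducials(peak, onset, offset, amp2, fs = fs)
  aa2 <- amplitude_area_features(rec, fid2)
  expect_equal(aa2$r_over_t, 2.5)
  expect_true(is.na(aa2$r_over_q))  # zero denominator is missing, not Inf
})

test_that("slopes follow the signed amplitude-over-time formula", {
  fs <- 1000
  peak <- wave_matrix(R = 1000, T = 1300, P = 800, nb = 1)  # T at +300 ms
  onset <- peak - 10; offset <- peak + 10
  amp <- wave_matrix(R = 1.0, T = 0.3, P = 1.0, nb = 1)
  fid <- make_fiducials(peak, onset, offset, amp, fs = fs)
  sl <- slope_features(fid)
  expect_equal(sl$slope_rt, (1.0 - 0.3) / (-0.3))  # -2.33 mV/s
  expect_equal(sl$slope_rp, 0)                     # equal amplitudes
  expect_true(is.na(sl$slope_rq))                  # absent wave
})

test_that("mobility and complexity match their analytic values", {
  set.seed(99)
  x <- rnorm(30000)
  mc <- mobility_complexity(x)
  expect_lt(abs(mc$mobility - 2), 0.05)  # var(diff) = 2 sigma^2

  fs <- 300; f <- 10
  s <- sin(2 * pi * f * (0:8999) / fs)
  mcs <- mobility_complexity(s)
  expect_equal(mcs$mobility, (2 * sin(pi * f / fs))^2, tolerance = 1e-3)

  expect_true(is.na(mobility_complexity(rep(3, 100))$mobility))
})

test_that("SVD beat features match rank structure and the Gram oracle", {
  beat <- sin(seq(0, 2 * pi, length.out = 51))
  m <- matrix(rep(beat, 10), nrow = 10, byrow = TRUE)
  sv <- svd_beat_features(m)
  expect_equal(length(sv), 45)
  expect_equal(sv[1], 1)
  expect_equal(sv[2:45], rep(0, 44))

  # two orthogonal beat shapes, norms 2:1, five each -> [1, 0.5, 0, ...]
  u <- c(2, rep(0, 50)); v <- c(0, 1, rep(0, 49))
  m2 <- rbind(matrix(rep(u, 5), 5, byrow = TRUE),
              matrix(rep(v, 5), 5, byrow = TRUE))
  sv2 <- svd_beat_features(m2)
  expect_equal(sv2[1:3], c(1, 0.5, 0))

  # 12 beats: entries 13..45 exactly zero
  set.seed(3)
  m3 <- matrix(rnorm(12 * 101), 12)
  sv3 <- svd_beat_features(m3)
  expect_true(all(sv3[13:45] == 0))
  expect_true(all(diff(sv3) <= 1e-12))         # non-increasing
  expect_true(all(sv3 >= 0 & sv3 <= 1))
  # Gram-matrix oracle on small matrices
  for (k in 1:5) {
    a <- matrix(rnorm(8 * 8), 8)
    d_oracle <- sqrt(sort(eigen(a %*% t(a), symmetric = TRUE)$values,
                          decreasing = TRUE))
    expect_equal(svd_beat_features(a)[1:8], (d_oracle / d_oracle[1]),
                 tolerance = 1e-8)
  }
  expect_true(all(is.na(svd_beat_features(matrix(0, 4, 10)))))
})

test_that("beatwise summaries are missing-aware", {
  expect_equal(summarize_beatwise(c(1, 2, 3)),
               list(mean = 2, median = 2, sd = 1))
  s1 <- summarize_beatwise(5)
  expect_equal(s1$mean, 5)
  expect_true(is.na(s1$sd))
  expect_equal(summarize_beatwise(c(1, NA, 3))$mean, 2)
  expect_true(all(is.na(unlist(summarize_beatwise(c(NA, NA))))))
})

test_that("assembled vectors have manifest length, plus plugin slot", {
  cfg <- quiet_sim_config(seed = 41)
  coh <- generate_cohort(cfg)
  r <- synth_ecg_record(coh[1, ], cfg, at = 9, rhythm_label = "sinus rhythm")
  rec <- notch_filter(bandpass_filter(r$record))
  paired <- data.frame(mean_gap_s = 42, age_years = 55)
  fv <- assemble_feature_vector(rec, paired)
  expect_equal(length(fv), 130)
  expect_equal(unname(fv["mean_gap_s"]), 42)
  plugin <- function(record) setNames(rep(0.5, 150), paste0("bs_", 1:150))
  fv2 <- assemble_feature_vector(rec, paired, external_plugin = plugin)
  expect_equal(length(fv2), 280)
  bad_plugin <- function(record) rep(1, 10)
  expect_error(assemble_feature_vector(rec, paired,
                                       external_plugin = bad_plugin),
               class = "ecgbp_plugin_error")
  expect_identical(fv, assemble_feature_vector(rec, paired))
})

test_that("features scale correctly under waveform amplification", {
  cfg <- quiet_sim_config(seed = 43, ecg_noise_sd = 0)
  coh <- generate_cohort(cfg)
  r <- synth_ecg_record(coh[1, ], cfg, at = 77, hr_true = 65,
                        rhythm_label = "sinus rhythm")
  rec <- r$record
  rec_scaled <- rec; rec_scaled$samples <- 3 * rec$samples
  f1 <- extract_record_features(rec)
  f3 <- extract_record_features(rec_scaled)
  man <- feature_manifest()
  interval_names <- man$name[man$group == "interval"]
  seg_level <- grep("seg_level", interval_names, value = TRUE)
  inv_names <- c(man$name[man$group %in% c("hjorth", "svd", "hrv")],
                 setdiff(interval_names, seg_level),
                 grep("^(r_over|snr)", man$name, value = TRUE))
  # segment levels are mean amplitudes, so they scale with the waveform
  scaled_names <- c(grep("^(amp_|area_|slope_|s_t_amp_diff)", man$name,
                         value = TRUE), seg_level)
  ok <- function(v) is.finite(v)
  i <- inv_names[ok(f1[inv_names]) & ok(f3[inv_names])]
  expect_equal(f3[i], f1[i], tolerance = 1e-6)
  s <- scaled_names[ok(f1[scaled_names]) & ok(f3[scaled_names])]
  expect_equal(f3[s], 3 * f1[s], tolerance = 1e-6)
})
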