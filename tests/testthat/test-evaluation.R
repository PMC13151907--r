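# Fold planning, CV mechanics, metrics, standards, categorization, operating
# points, central-tendency comparison.

toy_samples <- function(n_subj = 10, per = 2) {
  data.frame(record_id = paste0("R", seq_len(n_subj * per)),
             subject_id = rep(paste0("S", seq_len(n_subj)), each = per))
}

test_that("subject-wise folds isolate subjects and balance sizes", {
  s <- toy_samples(10, 3)
  plan <- make_folds(s, "subject_wise", k = 5, seed = 2)
  expect_setequal(names(plan$assignment), s$record_id)
  by_subj <- tapply(plan$assignment, s$subject_id[match(names(plan$assignment),
                                                        s$record_id)],
                    function(f) length(unique(f)))
  expect_true(all(by_subj == 1))
  subj_fold <- tapply(plan$assignment, s$subject_id, unique)
  expect_true(all(table(subj_fold) == 2))  # 10 subjects over 5 folds
  expect_identical(plan$assignment,
                   make_folds(s, "subject_wise", 5, seed = 2)$assignment)
  expect_error(make_folds(toy_samples(3), "subject_wise", k = 5),
               "subjects")
})

test_that("record-wise folds split within subjects", {
  s <- toy_samples(12, 4)
  plan <- make_folds(s, "record_wise", k = 5, seed = 3)
  spread <- tapply(plan$assignment, s$subject_id[match(names(plan$assignment),
                                                       s$record_id)],
                   function(f) length(unique(f)))
  expect_gt(mean(spread > 1), 0.5)  # most subjects span folds
  expect_true(max(table(plan$assignment)) -
                min(table(plan$assignment)) <= 1)
})

test_that("cross-validation predicts each record exactly once, identically across learners", {
  set.seed(5)
  n_subj <- 25
  samples <- data.frame(record_id = paste0("R", 1:(n_subj * 4)),
                        subject_id = rep(paste0("S", 1:n_subj), each = 4))
  samples$mean_sbp <- 120 + rnorm(nrow(samples), 0, 10)
  features <- data.frame(record_id = samples$record_id,
                         f1 = rnorm(nrow(samples)), f2 = rnorm(nrow(samples)))
  plan <- make_folds(samples, "subject_wise", 5, seed = 1)
  spec1 <- model_spec("regress_sbp", "random_forest", seed = 1)
  p1 <- run_cross_validation(samples, features, spec1, plan, min_n = 10)
  expect_equal(nrow(p1), nrow(samples))
  expect_false(anyDuplicated(p1$record_id) > 0)
  spec2 <- model_spec("regress_sbp", "xgboost", seed = 1)
  p2 <- run_cross_validation(samples, features, spec2, plan, min_n = 10)
  m <- match(p1$record_id, p2$record_id)
  expect_equal(p1$fold_id, p2$fold_id[m])  # identical fold membership
  p1b <- run_cross_validation(samples, features, spec1, plan, min_n = 10)
  expect_identical(p1$y_pred, p1b$y_pred)
})

test_that("regression metrics match worked examples and the degenerate-rho rule", {
  p <- data.frame(y_true = c(1, 2, 3, 4), y_pred = c(1, 2, 3, 4))
  m <- regression_metrics(p)
  expect_equal(m$mae, 0); expect_equal(m$me, 0); expect_equal(m$rho, 1)

  p2 <- data.frame(y_true = c(1, 2, 3, 4), y_pred = c(6, 7, 8, 9))
  m2 <- regression_metrics(p2)
  expect_equal(m2$me, 5); expect_equal(m2$sd_e, 0)
  expect_equal(m2$mae, 5); expect_equal(m2$rho, 1)

  p3 <- data.frame(y_true = c(100, 120, 140), y_pred = rep(120, 3))
  m3 <- regression_metrics(p3)
  expect_equal(m3$mae, 40 / 3)
  expect_equal(m3$me, 0)
  expect_true(is.na(m3$rho))
  expect_error(regression_metrics(p3[1, , drop = FALSE]), "2 predictions")
})

test_that("AAMI bounds are inclusive and apply to |ME|", {
  expect_true(aami_check(list(me = 0, sd_e = 0))$pass)
  expect_true(aami_check(list(me = 5.0, sd_e = 8.0))$pass)
  expect_true(aami_check(list(me = -5.0, sd_e = 8.0))$pass)
  expect_false(aami_check(list(me = 6.0, sd_e = 7.0))$pass)
  expect_false(aami_check(list(me = 0, sd_e = 8.1))$pass)
})

test_that("BHS grading reproduces the published grade table", {
  expect_equal(bhs_grade(bhs_pred(0.61, 0.86, 0.96))$grade, "A")
  expect_equal(bhs_grade(bhs_pred(0.60, 0.85, 0.95))$grade, "A")  # inclusive
  expect_equal(bhs_grade(bhs_pred(0.55, 0.80, 0.92))$grade, "B")
  expect_equal(bhs_grade(bhs_pred(0.45, 0.70, 0.86))$grade, "C")
  expect_equal(bhs_grade(bhs_pred(0.30, 0.50, 0.60))$grade, "fail")
  # all three thresholds must hold simultaneously
  expect_equal(bhs_grade(bhs_pred(0.70, 0.80, 0.92))$grade, "B")
  cum <- bhs_grade(bhs_pred(0.45, 0.70, 0.86))$cumulative
  expect_true(all(diff(cum) >= 0))
})

test_that("degrading predictions never improves the BHS grade", {
  set.seed(8)
  n <- 2000
  y <- 120 + rnorm(n, 0, 15)
  base_pred <- y + rnorm(n, 0, 4)
  rank_of <- c(A = 1, B = 2, C = 3, fail = 4)
  grades <- vapply(c(0, 4, 8, 16), function(extra) {
    p <- data.frame(y_true = y, y_pred = base_pred + rnorm(n, 0, extra))
    rank_of[[bhs_grade(p)$grade]]
  }, numeric(1))
  expect_true(all(diff(grades) >= 0))
})

test_that("BP categorization matches examples and the truth-table oracle", {
  expect_equal(bp_categorize(119, 79), "Normal")
  expect_equal(bp_categorize(125, 85), "Stage1")
  expect_equal(bp_categorize(141, 79), "Stage2")
  expect_equal(bp_categorize(125, 75), "Elevated")
  expect_equal(bp_categorize(119, 89), "Stage1")
  expect_error(bp_categorize(-1, 80), "positive")
  grid <- expand.grid(sbp = 118:142, dbp = 78:92)
  expect_equal(bp_categorize(grid$sbp, grid$dbp),
               unname(bp_category_oracle(grid$sbp, grid$dbp)))
})

test_that("binary grouping collapses to non-hypertensive vs hypertensive", {
  expect_equal(binary_bp_label(c("Normal", "Elevated", "Stage1", "Stage2")),
               c(0L, 0L, 1L, 1L))
})

test_that("AUROC equals pair enumeration on all 6-record arrangements", {
  score <- c(0.05, 0.2, 0.4, 0.6, 0.8, 0.95)
  for (bits in 1:62) {  # skip all-0 (0) and all-1 (63)
    label <- as.integer(intToBits(bits))[1:6]
    expect_equal(auroc(score, label), auroc_pairs(score, label))
  }
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)  # anti-ranking
  # ties handled by average rank; cross-check against pROC when available
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(2)
    s <- sample(seq(0, 1, 0.1), 40, replace = TRUE)
    l <- rbinom(40, 1, 0.5)
    expect_equal(auroc(s, l),
                 as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                levels = c(0, 1),
                                                direction = "<"))))
  }
})

test_that("the sensitivity-anchored operating point behaves as specified", {
  pred <- data.frame(score = c(0.9, 0.85, 0.8, 0.7, 0.3, 0.2, 0.1, 0.05),
                     y_true = c(1, 1, 1, 1, 0, 0, 0, 0))
  cm <- classification_metrics_at_sensitivity(pred, anchor = 0.7)
  expect_equal(cm$auroc, 1.0)
  expect_equal(cm$specificity, 1.0)
  expect_equal(cm$ppv, 1.0)
  expect_gte(cm$sensitivity, 0.7)
  # threshold is the largest achieving the anchor: sensitivity 0.75 here
  expect_equal(cm$sensitivity, 0.75)
  expect_error(classification_metrics_at_sensitivity(
    data.frame(score = c(0.2, 0.4), y_true = c(1, 1))), "single-class")
})

test_that("central-tendency comparison flags constant-like models", {
  set.seed(9)
  y <- 120 + rnorm(300, 0, 12)
  med <- median(y)
  p_model <- data.frame(y_true = y, y_pred = rep(med, 300))
  p_base <- list(median = data.frame(y_true = y, y_pred = rep(med, 300)),
                 mean = data.frame(y_true = y, y_pred = rep(mean(y), 300)))
  res <- central_tendency_comparison(p_model, p_base)
  expect_true(res$central_tendency)
  expect_equal(res$table$mae[res$table$predictor == "model"],
               res$table$mae[res$table$predictor == "median"])

  p_good <- data.frame(y_true = y, y_pred = y + rnorm(300, 0, 2))
  res2 <- central_tendency_comparison(p_good, p_base)
  expect_false(res2$central_tendency)
})

test_that("bootstrap CI for rho covers the truth on correlated data", {
  set.seed(10)
  n <- 400
  subj <- rep(paste0("S", 1:100), each = 4)
  y <- rnorm(n)
  p <- data.frame(subject_id = subj, y_true = y, y_pred = y + rnorm(n, 0, 1))
  ci <- bootstrap_rho_ci(p, n_boot = 300, seed = 4)
  expect_true(ci$lower < ci$rho && ci$rho < ci$upper)
  expect_gt(ci$lower, 0.4)
})
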