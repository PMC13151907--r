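## Evaluation layer: cross-validation planning (subject-wise vs record-wise),
## regression and classification metrics, AAMI / BHS device standards, AHA BP
## categorization and the central-tendency baseline comparison.

#' Plan cross-validation folds
#'
#' Subject-wise plans assign whole subjects to folds so no individual spans
#' train and test (leakage prevention); record-wise plans shuffle records
#' regardless of subject. Fold sizes are balanced within one unit (subjects
#' or records, per mode). Deterministic per seed.
#'
#' @param samples paired-sample data.frame (`record_id`, `subject_id`).
#' @param mode `"subject_wise"` or `"record_wise"`.
#' @param k number of folds.
#' @param seed integer seed.
#' @return object of class `fold_plan`: `mode`, `k`, `assignment` (named
#'   integer vector record_id -> fold), `seed`.
#' @export
make_folds <- function(samples, mode = c("subject_wise", "record_wise"),
                       k = 5L, seed = 1L) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  if (mode == "subject_wise") {
    subjects <- unique(samples$subject_id)
    if (length(subjects) < k)
      ecgbp_stop("ecgbp_data_error",
                 "subject_wise CV needs >= %d subjects, got %d",
                 k, length(subjects))
    fold_of <- with_seed(derive_seed(seed, "folds", mode, k), {
      stats::setNames(rep_len(seq_len(k), length(subjects)),
                      sample(subjects))
    })
    assignment <- stats::setNames(unname(fold_of[samples$subject_id]),
                                  samples$record_id)
  } else {
    if (nrow(samples) < k)
      ecgbp_stop("ecgbp_data_error", "record_wise CV needs >= %d records", k)
    assignment <- with_seed(derive_seed(seed, "folds", mode, k), {
      stats::setNames(rep_len(seq_len(k), nrow(samples)),
                      sample(samples$record_id))
    })
    assignment <- assignment[samples$record_id]
  }
  structure(list(mode = mode, k = k, assignment = assignment, seed = seed),
            class = "fold_plan")
}

#' Run cross-validation for one model spec
#'
#' Trains on k-1 folds and predicts the held-out fold, for every fold;
#' predictions from all folds are pooled (each record predicted exactly once)
#' before metric computation. All learners given the same plan see identical
#' train/test memberships.
#'
#' @param samples paired-sample data.frame carrying the targets.
#' @param features feature data.frame (`record_id` + feature columns).
#' @param spec a [model_spec()].
#' @param plan a [make_folds()] plan covering all samples.
#' @param min_n minimum per-fold training size (passed to the trainers).
#' @return a `prediction_set` data.frame: `fold_id`, `record_id`,
#'   `subject_id`, `y_true`, `y_pred` (regression) or `score`, `class_pred`
#'   (classification; class at score 0.5).
#' @export
run_cross_validation <- function(samples, features, spec, plan, min_n = 50L) {
  tcol <- target_column(spec$task)
  if (!tcol %in% names(samples))
    ecgbp_stop("ecgbp_data_error", "samples lack target column '%s'", tcol)
  m <- match(samples$record_id, features$record_id)
  if (anyNA(m))
    ecgbp_stop("ecgbp_data_error", "%d samples have no feature row",
               sum(is.na(m)))
  fx <- features[m, setdiff(names(features), "record_id"), drop = FALSE]
  fold <- unname(plan$assignment[samples$record_id])
  if (anyNA(fold))
    ecgbp_stop("ecgbp_data_error", "fold plan does not cover all samples")
  classify <- spec$task == "classify_bp"
  out <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    if (!any(tr))
      ecgbp_stop("ecgbp_data_error", "fold %d has an empty training set", f)
    model <- if (classify)
      train_classifier(fx[tr, , drop = FALSE], samples[[tcol]][tr], spec,
                       min_n = min_n)
    else
      train_regressor(fx[tr, , drop = FALSE], samples[[tcol]][tr], spec,
                      min_n = min_n)
    p <- predict(model, fx[te, , drop = FALSE])
    out[[f]] <- if (classify)
      data.frame(fold_id = f, record_id = samples$record_id[te],
                 subject_id = samples$subject_id[te],
                 y_true = samples[[tcol]][te], score = p,
                 class_pred = as.integer(p >= 0.5))
    else
      data.frame(fold_id = f, record_id = samples$record_id[te],
                 subject_id = samples$subject_id[te],
                 y_true = samples[[tcol]][te], y_pred = p)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("prediction_set", "data.frame")
  res
}

#' Aggregate regression metrics
#'
#' Errors are prediction minus truth: ME = mean error, SD-E = sample SD of
#' errors, MAE = mean absolute error, SD-AE = sample SD of absolute errors,
#' rho = Pearson correlation of truth and prediction. rho is reported as NA
#' (undefined) when either side is constant — a constant predictor is
#' exactly the central-tendency case and must not fake a correlation.
#'
#' @param pred a `prediction_set` (needs `y_true`, `y_pred`).
#' @return list `mae`, `sd_ae`, `me`, `sd_e`, `rho`, `n`.
#' @export
regression_metrics <- function(pred) {
  if (nrow(pred) < 2) ecgbp_stop("ecgbp_data_error", "need >= 2 predictions")
  e <- pred$y_pred - pred$y_true
  rho <- if (stats::sd(pred$y_true) == 0 || stats::sd(pred$y_pred) == 0)
    NA_real_ else stats::cor(pred$y_true, pred$y_pred)
  list(mae = mean(abs(e)), sd_ae = stats::sd(abs(e)),
       me = mean(e), sd_e = stats::sd(e), rho = rho, n = nrow(pred))
}

#' AAMI device-standard check
#'
#' Pass iff |ME| <= 5 mmHg and SD of error <= 8 mmHg (inclusive bounds; the
#' standard bounds the error magnitude).
#'
#' @param metrics a [regression_metrics()] result.
#' @return list `pass`, `me`, `sd_e`.
#' @export
aami_check <- function(metrics) {
  list(pass = abs(metrics$me) <= 5 && metrics$sd_e <= 8,
       me = metrics$me, sd_e = metrics$sd_e)
}

#' BHS cumulative-error grading
#'
#' Cumulative percentages of absolute errors within 5, 10 and 15 mmHg
#' (inclusive); the grade is the best row of the BHS table whose three
#' thresholds are all met: A = (60, 85, 95)%, B = (50, 75, 90)%,
#' C = (40, 65, 85)%, otherwise fail.
#'
#' @param pred a `prediction_set`.
#' @return list `cumulative` (named percentages), `grade`.
#' @export
bhs_grade <- function(pred) {
  ae <- abs(pred$y_pred - pred$y_true)
  cum <- c(within5 = 100 * mean(ae <= 5),
           within10 = 100 * mean(ae <= 10),
           within15 = 100 * mean(ae <= 15))
  thresholds <- list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))
  grade <- "fail"
  for (g in c("A", "B", "C")) {
    if (all(cum >= thresholds[[g]])) { grade <- g; break }
  }
  list(cumulative = cum, grade = grade)
}

#' AHA blood-pressure categorization
#'
#' Highest-stage-first evaluation (clinical convention; the raw table is not
#' mutually exclusive at face value): Stage 2 if SBP >= 140 or DBP >= 90;
#' else Stage 1 if SBP in 130-139 or DBP in 80-89; else Elevated if SBP in
#' 120-129 (DBP necessarily < 80 here); else Normal.
#'
#' @param sbp,dbp numeric, mmHg; must be positive.
#' @return character vector in `{"Normal", "Elevated", "Stage1", "Stage2"}`.
#' @export
bp_categorize <- function(sbp, dbp) {
  if (any(!is.finite(sbp) | !is.finite(dbp) | sbp <= 0 | dbp <= 0))
    ecgbp_stop("ecgbp_data_error", "BP values must be positive and finite")
  out <- rep("Normal", length(sbp))
  out[sbp >= 120 & sbp <= 129 & dbp < 80] <- "Elevated"
  out[(sbp >= 130 & sbp <= 139) | (dbp >= 80 & dbp <= 89)] <- "Stage1"
  out[sbp >= 140 | dbp >= 90] <- "Stage2"
  out
}

#' Binary BP class from the four categories
#'
#' Normal and Elevated collapse to the non-hypertensive class (0); Stage 1
#' and Stage 2 to the hypertensive class (1).
#'
#' @param category character vector from [bp_categorize()].
#' @return integer vector, 0 = normal_class, 1 = hypertensive_class.
#' @export
binary_bp_label <- function(category) {
  stopifnot(all(category %in% c("Normal", "Elevated", "Stage1", "Stage2")))
  as.integer(category %in% c("Stage1", "Stage2"))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with average ranks for ties.
#'
#' @param score numeric scores.
#' @param label 0/1 labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(score, label) {
  pos <- label == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    ecgbp_stop("ecgbp_data_error", "AUROC needs both classes")
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average-precision form: sum over descending-score groups of precision
#' times the recall increment (tied scores handled as one group).
#'
#' @inheritParams auroc
#' @return AUPR in `(0, 1]`.
#' @export
aupr <- function(score, label) {
  n1 <- sum(label == 1)
  if (n1 == 0 || all(label == 1))
    ecgbp_stop("ecgbp_data_error", "AUPR needs both classes")
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- label[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  tp <- cumsum(tp_g); nn <- cumsum(n_g)
  precision <- tp / nn
  recall <- tp / n1
  d_recall <- diff(c(0, recall))
  sum(precision * d_recall)
}

#' Classification metrics at a sensitivity-anchored operating point
#'
#' AUROC and AUPR are threshold-free; the operating point is the largest
#' score threshold achieving sensitivity >= `anchor` (the feasible point
#' closest from above; ties break toward higher specificity). Point metrics
#' (accuracy, F1, specificity, PPV, NPV, realized sensitivity) are computed
#' at that threshold.
#'
#' @param pred a classification `prediction_set` (`score`, `y_true` in 0/1).
#' @param anchor target sensitivity (default 0.7).
#' @return list of metrics plus `threshold_used`.
#' @export
classification_metrics_at_sensitivity <- function(pred, anchor = 0.7) {
  y <- as.integer(pred$y_true); s <- pred$score
  if (length(unique(y)) < 2)
    ecgbp_stop("ecgbp_data_error", "single-class test set")
  thr_cand <- sort(unique(s), decreasing = TRUE)
  sens_at <- vapply(thr_cand, function(t) mean(s[y == 1] >= t), numeric(1))
  ok <- which(sens_at >= anchor)
  thr <- thr_cand[ok[1]]  # largest threshold (highest specificity) that works
  pred_pos <- s >= thr
  tp <- sum(pred_pos & y == 1); fp <- sum(pred_pos & y == 0)
  fn <- sum(!pred_pos & y == 1); tn <- sum(!pred_pos & y == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  list(auroc = auroc(s, y),
       aupr = aupr(s, y),
       f1 = if (is.na(precision) || precision + recall == 0) NA_real_
            else 2 * precision * recall / (precision + recall),
       accuracy = (tp + tn) / length(y),
       specificity = tn / (tn + fp),
       ppv = precision,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       sensitivity = recall,
       sensitivity_anchor = anchor,
       threshold_used = thr)
}

#' Compare a model against fixed central-tendency baselines
#'
#' Computes MAE/SD-AE/ME/SD-E for the model and each fixed baseline on the
#' identical test records, and flags the central-tendency regime when the
#' model's MAE is at least 95% of the median baseline's MAE (i.e. the model
#' is practically indistinguishable from predicting the training median).
#'
#' @param pred_model the model's `prediction_set`.
#' @param pred_baselines named list of baseline `prediction_set`s (must
#'   include `median`).
#' @return list `table` (one metrics row per predictor) and
#'   `central_tendency` flag.
#' @export
central_tendency_comparison <- function(pred_model, pred_baselines) {
  stopifnot("median" %in% names(pred_baselines))
  one <- function(p, name) {
    m <- regression_metrics(p)
    data.frame(predictor = name, mae = m$mae, sd_ae = m$sd_ae,
               me = m$me, sd_e = m$sd_e, n = m$n)
  }
  tab <- rbind(one(pred_model, "model"),
               do.call(rbind, Map(one, pred_baselines,
                                  names(pred_baselines))))
  rownames(tab) <- NULL
  model_mae <- tab$mae[tab$predictor == "model"]
  med_mae <- tab$mae[tab$predictor == "median"]
  list(table = tab,
       central_tendency = model_mae >= 0.95 * med_mae)
}

#' Bootstrap confidence interval for the CV correlation
#'
#' Percentile bootstrap over subjects (clusters), seeded.
#'
#' @param pred a regression `prediction_set`.
#' @param n_boot number of resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @return list `rho`, `lower`, `upper`.
#' @export
bootstrap_rho_ci <- function(pred, n_boot = 1000L, level = 0.95, seed = 1L) {
  by_subj <- split(seq_len(nrow(pred)), pred$subject_id)
  subj <- names(by_subj)
  rhos <- with_seed(derive_seed(seed, "bootrho"), {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample(subj, length(subj), replace = TRUE)
      idx <- unlist(by_subj[pick], use.names = FALSE)
      if (stats::sd(pred$y_true[idx]) == 0 || stats::sd(pred$y_pred[idx]) == 0)
        return(NA_real_)
      stats::cor(pred$y_true[idx], pred$y_pred[idx])
    }, numeric(1))
  })
  a <- (1 - level) / 2
  list(rho = stats::cor(pred$y_true, pred$y_pred),
       lower = stats::quantile(rhos, a, na.rm = TRUE, names = FALSE),
       upper = stats::quantile(rhos, 1 - a, na.rm = TRUE, names = FALSE))
}
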