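## Sex- and rhythm-stratified tree-ensemble regression / classification, plus
## fixed central-tendency baselines. The learner registry ships random_forest
## and extra_trees (via ranger) and xgboost (gradient boosting); all learners
## are deterministic given (data, spec seed) and run on identical fold data.

.learner_registry <- new.env(parent = emptyenv())

#' Register a learner
#'
#' A learner is a list with elements `fit(x, y, task, hyper, seed)` returning
#' an opaque fit and `predict(fit, x, task)` returning numeric predictions
#' (probabilities of the positive class for classification).
#'
#' @param name learner name.
#' @param learner the learner list.
#' @return `name`, invisibly.
#' @export
register_learner <- function(name, learner) {
  stopifnot(is.function(learner$fit), is.function(learner$predict))
  assign(name, learner, envir = .learner_registry)
  invisible(name)
}

#' Names of registered learners
#' @return character vector.
#' @export
registered_learners <- function() sort(ls(.learner_registry))

# median imputation fitted on training data only; ranger cannot take NAs
fit_imputer <- function(x) {
  med <- vapply(as.data.frame(x), function(col)
    stats::median(col[is.finite(col)]) , numeric(1))
  med[!is.finite(med)] <- 0
  med
}
apply_imputer <- function(x, med) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    bad <- !is.finite(x[[j]])
    if (any(bad)) x[[j]][bad] <- med[j]
  }
  x
}

ranger_learner <- function(splitrule_reg, splitrule_cls, extra = list()) {
  list(
    fit = function(x, y, task, hyper, seed) {
      med <- fit_imputer(x)
      dat <- apply_imputer(x, med)
      dat$..y <- if (task == "classify") factor(y, levels = c(0, 1)) else y
      args <- utils::modifyList(list(
        formula = ..y ~ ., data = dat,
        num.trees = 300, seed = seed, num.threads = 1,
        respect.unordered.factors = TRUE,
        probability = task == "classify",
        splitrule = if (task == "classify") splitrule_cls else splitrule_reg
      ), utils::modifyList(extra, hyper))
      list(model = do.call(ranger::ranger, args), imputer = med)
    },
    predict = function(fit, x, task) {
      dat <- apply_imputer(x, fit$imputer)
      pr <- stats::predict(fit$model, data = dat, num.threads = 1)$predictions
      if (task == "classify") pr[, "1"] else pr
    }
  )
}

xgboost_learner <- function() {
  list(
    fit = function(x, y, task, hyper, seed) {
      # frozen conservative defaults: BP-style tabular data has weak signal
      # and subject-level noise, so shallow, strongly regularized boosting
      defaults <- list(nrounds = 100, eta = 0.05, max_depth = 3,
                       subsample = 0.9, colsample_bytree = 0.9,
                       min_child_weight = 20, lambda = 10)
      hp <- utils::modifyList(defaults, hyper)
      params <- c(hp[setdiff(names(hp), "nrounds")],
                  list(objective = if (task == "classify")
                         "binary:logistic" else "reg:squarederror",
                       nthread = 1, seed = seed))
      dm <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
      set.seed(seed)
      list(model = xgboost::xgb.train(params, dm, nrounds = hp$nrounds,
                                      verbose = 0),
           features = colnames(x))
    },
    predict = function(fit, x, task) {
      stats::predict(fit$model, xgboost::xgb.DMatrix(as.matrix(x)))
    }
  )
}

register_learner("random_forest", ranger_learner("variance", "gini"))
register_learner("extra_trees",
                 ranger_learner("extratrees", "extratrees",
                                extra = list(num.random.splits = 1)))
register_learner("xgboost", xgboost_learner())

#' Model specification
#'
#' @param task `"regress_sbp"`, `"regress_dbp"` or `"classify_bp"`.
#' @param learner a registered learner name.
#' @param hyperparams named list overriding the learner's frozen defaults.
#' @param seed integer seed; required for reproducibility.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(task = c("regress_sbp", "regress_dbp", "classify_bp"),
                       learner = "random_forest", hyperparams = list(),
                       seed = 1L) {
  task <- match.arg(task)
  if (!learner %in% registered_learners())
    ecgbp_stop("ecgbp_config_error", "unknown learner '%s'; registered: %s",
               learner, paste(registered_learners(), collapse = ", "))
  if (is.null(seed)) ecgbp_stop("ecgbp_config_error", "seed must be set")
  structure(list(task = task, learner = learner, hyperparams = hyperparams,
                 seed = as.integer(seed)), class = "model_spec")
}

#' Select one analysis stratum
#'
#' Strata are the four sex-by-label-scope cells: `male`/`female` crossed with
#' `all` records or `normal` (sinus rhythm) only.
#'
#' @param samples paired-sample data.frame (with `sex`, `is_normal`).
#' @param sex `"male"` or `"female"`.
#' @param label_scope `"all"` or `"normal"`.
#' @return the filtered data.frame.
#' @export
stratify_dataset <- function(samples, sex = c("male", "female"),
                             label_scope = c("all", "normal")) {
  sex <- match.arg(sex)
  label_scope <- match.arg(label_scope)
  out <- samples[samples$sex == sex, , drop = FALSE]
  if (label_scope == "normal") out <- out[out$is_normal, , drop = FALSE]
  out
}

target_column <- function(task) switch(task,
  regress_sbp = "mean_sbp", regress_dbp = "mean_dbp",
  classify_bp = "bp_class")

#' Train a regression model
#'
#' @param x feature data.frame/matrix (numeric; NAs allowed).
#' @param y numeric target vector.
#' @param spec a [model_spec()] with a regression task.
#' @param min_n minimum training-set size.
#' @return object of class `ecgbp_model` with a [predict][predict.ecgbp_model]
#'   method. A zero-variance target yields a constant model with a warning.
#' @export
train_regressor <- function(x, y, spec, min_n = 50L) {
  if (nrow(x) < min_n)
    ecgbp_stop("ecgbp_data_error", "need >= %d training records, got %d",
               min_n, nrow(x))
  if (any(!is.finite(y)))
    ecgbp_stop("ecgbp_data_error", "targets must be finite")
  if (stats::sd(y) == 0) {
    warning("degenerate (zero-variance) target; trained constant model")
    return(structure(list(kind = "constant", value = y[1], spec = spec,
                          degenerate = TRUE), class = "ecgbp_model"))
  }
  lrn <- get(spec$learner, envir = .learner_registry)
  fit <- lrn$fit(x, y, "regress", spec$hyperparams, spec$seed)
  structure(list(kind = "learner", fit = fit, learner = lrn, spec = spec),
            class = "ecgbp_model")
}

#' Train a binary classifier
#'
#' @param x feature data.frame/matrix.
#' @param y binary labels coded 0/1 (1 = positive/hypertensive class).
#' @param spec a [model_spec()].
#' @param min_n minimum training-set size.
#' @return an `ecgbp_model` whose predictions are positive-class scores in
#'   `[0, 1]` (the ensemble's probability output, not recalibrated).
#' @export
train_classifier <- function(x, y, spec, min_n = 50L) {
  if (nrow(x) < min_n)
    ecgbp_stop("ecgbp_data_error", "need >= %d training records, got %d",
               min_n, nrow(x))
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)))
    ecgbp_stop("ecgbp_data_error", "labels must be 0/1")
  if (length(unique(y)) == 1) {
    warning("single-class training labels; trained constant-score model")
    return(structure(list(kind = "constant", value = y[1], spec = spec,
                          degenerate = TRUE), class = "ecgbp_model"))
  }
  lrn <- get(spec$learner, envir = .learner_registry)
  fit <- lrn$fit(x, y, "classify", spec$hyperparams, spec$seed)
  structure(list(kind = "learner", fit = fit, learner = lrn, spec = spec,
                 classify = TRUE), class = "ecgbp_model")
}

#' Predict from a trained model
#'
#' @param object an `ecgbp_model`.
#' @param newdata feature data.frame/matrix.
#' @param ... unused.
#' @return numeric predictions (scores for classifiers).
#' @export
predict.ecgbp_model <- function(object, newdata, ...) {
  if (object$kind == "constant") return(rep(object$value, nrow(newdata)))
  task <- if (isTRUE(object$classify)) "classify" else "regress"
  as.numeric(object$learner$predict(object$fit, newdata, task))
}

#' @export
print.ecgbp_model <- function(x, ...) {
  cat(sprintf("<ecgbp_model> %s / %s%s\n", x$spec$task, x$spec$learner,
              if (x$kind == "constant") " (degenerate constant)" else ""))
  invisible(x)
}

#' Fixed central-tendency baseline predictor
#'
#' Predicts the training targets' mean, median or mode for every test record.
#' The mode is computed on integer-rounded mmHg (ties broken toward the
#' smallest value).
#'
#' @param train_targets numeric training targets.
#' @param kind `"mean"`, `"median"` or `"mode"`.
#' @return an `ecgbp_model` predicting a constant.
#' @export
fixed_baseline_estimator <- function(train_targets,
                                     kind = c("mean", "median", "mode")) {
  kind <- match.arg(kind)
  if (length(train_targets) == 0)
    ecgbp_stop("ecgbp_data_error", "empty training targets")
  value <- switch(kind,
    mean = mean(train_targets),
    median = stats::median(train_targets),
    mode = {
      tab <- table(round(train_targets))
      as.numeric(names(tab)[which.max(tab)])
    })
  structure(list(kind = "constant", value = value, baseline = kind),
            class = "ecgbp_model")
}
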