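## Experiment orchestration: simulate -> clean -> features -> train ->
## evaluate under a single root seed, with a consolidated report. Every
## stage's randomness derives from the root seed, so re-running an identical
## configuration reproduces identical reports byte for byte.

#' Build an experiment configuration
#'
#' @param n_subjects cohort size.
#' @param root_seed root seed for every random stream.
#' @param sim named list of [sim_config()] overrides.
#' @param clean named list of [clean_config()] overrides.
#' @param filter named list of [filter_config()] overrides.
#' @param learners registered learner names to run (all on identical folds).
#' @param tasks subset of `regress_sbp`, `regress_dbp`, `classify_bp`.
#' @param strata data.frame with columns `sex`, `label_scope`; default all
#'   four sex-by-scope cells.
#' @param cv_mode `"subject_wise"` (default) or `"record_wise"`.
#' @param k folds.
#' @param min_train minimum per-fold training size.
#' @param out_dir optional output directory for stage files.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 200L, root_seed = 1L,
                              sim = list(), clean = list(), filter = list(),
                              learners = "random_forest",
                              tasks = c("regress_sbp", "regress_dbp",
                                        "classify_bp"),
                              strata = expand.grid(
                                sex = c("male", "female"),
                                label_scope = c("all", "normal"),
                                stringsAsFactors = FALSE),
                              cv_mode = "subject_wise", k = 5L,
                              min_train = 50L, out_dir = NULL) {
  stopifnot(all(tasks %in% c("regress_sbp", "regress_dbp", "classify_bp")))
  missing_learners <- setdiff(learners, registered_learners())
  if (length(missing_learners))
    ecgbp_stop("ecgbp_config_error", "unregistered learners: %s",
               paste(missing_learners, collapse = ", "))
  structure(as.list(environment()), class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' The YAML mirrors [experiment_config()] arguments, with per-stage blocks
#' `sim:`, `clean:`, `filter:`.
#'
#' @param path YAML file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(experiment_config)))]
  # YAML maps with a `kind` key describe distributions
  for (block in intersect(c("sim", "clean", "filter"), names(args))) {
    args[[block]] <- lapply(args[[block]], function(v) {
      if (is.list(v) && !is.null(v$kind)) do.call(dist_spec, v) else v
    })
  }
  if (!is.null(args$strata)) args$strata <- as.data.frame(args$strata)
  do.call(experiment_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    ecgbp_stop("ecgbp_stage_error", "stage '%s' failed: %s", name,
               conditionMessage(e))
  })
}

# per-fold fixed baselines predicted on the identical test records
run_fixed_baselines <- function(samples, plan, tcol) {
  fold <- unname(plan$assignment[samples$record_id])
  out <- list()
  for (kind in c("mean", "median", "mode")) {
    rows <- lapply(seq_len(plan$k), function(f) {
      te <- fold == f
      if (!any(te)) return(NULL)
      bl <- fixed_baseline_estimator(samples[[tcol]][fold != f], kind)
      data.frame(fold_id = f, record_id = samples$record_id[te],
                 subject_id = samples$subject_id[te],
                 y_true = samples[[tcol]][te],
                 y_pred = rep(bl$value, sum(te)))
    })
    p <- do.call(rbind, rows)
    class(p) <- c("prediction_set", "data.frame")
    out[[kind]] <- p
  }
  out
}

#' Run a full experiment
#'
#' Simulates the cohort, cleans and pairs it, extracts features, and for
#' every stratum x task x learner runs cross-validation and the evaluation
#' battery (regression metrics, AAMI, BHS, central-tendency baseline
#' comparison; classification metrics at the 0.7-sensitivity operating
#' point). Any stage error aborts with the stage name and reason.
#'
#' @param config an [experiment_config()].
#' @return object of class `ecgbp_experiment`: list with `config_digest`,
#'   `report` (nested per stratum/task/learner), `predictions`, `paired`,
#'   `features`, and the `cleaning` report.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  root <- config$root_seed

  sim_cfg <- stage("config", do.call(sim_config, c(
    list(n_subjects = config$n_subjects, seed = derive_seed(root, "sim")),
    config$sim)))
  study <- stage("simulate", simulate_study(sim_cfg))
  clean_cfg <- stage("config", do.call(clean_config, c(
    list(cap_seed = derive_seed(root, "cap")), config$clean)))
  cleaned <- stage("clean", clean_cohort(study, clean_cfg))
  paired <- cleaned$paired
  if (nrow(paired) == 0)
    ecgbp_stop("ecgbp_stage_error", "stage 'clean' left no paired samples")
  filter_cfg <- do.call(filter_config, config$filter)
  features <- stage("features",
                    extract_features(study, paired, filter_cfg = filter_cfg))
  paired <- paired[paired$record_id %in% features$record_id, , drop = FALSE]
  paired$bp_class <- binary_bp_label(bp_categorize(paired$mean_sbp,
                                                   paired$mean_dbp))

  report <- list()
  predictions <- list()
  for (si in seq_len(nrow(config$strata))) {
    sx <- config$strata$sex[si]; sc <- config$strata$label_scope[si]
    sname <- paste(sx, sc, sep = "_")
    ds <- stratify_dataset(paired, sx, sc)
    if (nrow(ds) == 0)
      ecgbp_stop("ecgbp_stage_error",
                 "stage 'stratify' produced an empty dataset for %s", sname)
    plan <- stage("folds", make_folds(ds, config$cv_mode, config$k,
                                      seed = derive_seed(root, "cv", sname)))
    for (task in config$tasks) {
      tcol <- target_column(task)
      for (lrn in config$learners) {
        spec <- model_spec(task, lrn,
                           seed = derive_seed(root, "model", sname, task, lrn))
        pred <- stage("cross_validation",
                      run_cross_validation(ds, features, spec, plan,
                                           min_n = config$min_train))
        key <- paste(sname, task, lrn, sep = ".")
        predictions[[key]] <- pred
        entry <- list(stratum = sname, task = task, learner = lrn,
                      n_records = nrow(ds),
                      n_subjects = length(unique(ds$subject_id)))
        if (task == "classify_bp") {
          entry$classification <-
            stage("evaluate", classification_metrics_at_sensitivity(pred))
        } else {
          met <- stage("evaluate", regression_metrics(pred))
          baselines <- run_fixed_baselines(ds, plan, tcol)
          entry$regression <- met
          entry$aami <- aami_check(met)
          entry$bhs <- bhs_grade(pred)
          entry$baseline_comparison <-
            central_tendency_comparison(pred, baselines)
        }
        report[[key]] <- entry
      }
    }
  }

  bundle <- structure(list(
    config = config,
    seed = root,
    n_subjects = config$n_subjects,
    cleaning = cleaned$report,
    report = report,
    predictions = predictions,
    paired = paired,
    features = features
  ), class = "ecgbp_experiment")

  if (!is.null(config$out_dir)) export_report(bundle, c("json", "md"))
  bundle
}

#' Export an experiment report
#'
#' JSON export writes `eval_report.json` (full nested report plus the
#' cleaning ledger); markdown export writes `eval_report.md` with one
#' section per stratum x task. Classification runs additionally export
#' `roc_pr_points.csv` with the pooled ROC and PR curve points.
#'
#' @param bundle an `ecgbp_experiment`.
#' @param format subset of `"json"`, `"md"`.
#' @param dir output directory; defaults to the config's `out_dir`.
#' @return character vector of files written, invisibly.
#' @export
export_report <- function(bundle, format = "json", dir = NULL) {
  stopifnot(inherits(bundle, "ecgbp_experiment"))
  if (length(bundle$report) == 0)
    ecgbp_stop("ecgbp_data_error", "empty report bundle")
  if (is.null(dir)) dir <- bundle$config$out_dir
  if (is.null(dir)) ecgbp_stop("ecgbp_config_error", "no output directory")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if ("json" %in% format) {
    f <- file.path(dir, "eval_report.json")
    jsonlite::write_json(
      list(seed = bundle$seed, n_subjects = bundle$n_subjects,
           cleaning = bundle$cleaning, results = bundle$report),
      f, auto_unbox = TRUE, digits = 10, pretty = TRUE, na = "null")
    written <- c(written, f)
  }
  if ("md" %in% format) {
    f <- file.path(dir, "eval_report.md")
    lines <- c("# Experiment report", "",
               sprintf("Seed %d, %d subjects.", bundle$seed,
                       bundle$n_subjects), "")
    for (entry in bundle$report) {
      lines <- c(lines, sprintf("## %s / %s / %s", entry$stratum, entry$task,
                                entry$learner), "")
      if (!is.null(entry$regression)) {
        m <- entry$regression
        lines <- c(lines, sprintf(
          "- MAE %.2f (SD %.2f), ME %.2f (SD %.2f), rho %s, n = %d",
          m$mae, m$sd_ae, m$me, m$sd_e,
          ifelse(is.na(m$rho), "undefined", sprintf("%.3f", m$rho)), m$n),
          sprintf("- AAMI: %s; BHS grade: %s",
                  ifelse(entry$aami$pass, "pass", "fail"), entry$bhs$grade),
          sprintf("- Central-tendency regime: %s",
                  entry$baseline_comparison$central_tendency), "")
      }
      if (!is.null(entry$classification)) {
        cm <- entry$classification
        lines <- c(lines, sprintf(
          "- AUROC %.3f, AUPR %.3f, F1 %.3f, accuracy %.3f at sensitivity %.2f",
          cm$auroc, cm$aupr, cm$f1, cm$accuracy, cm$sensitivity), "")
      }
    }
    writeLines(lines, f)
    written <- c(written, f)
  }
  cls <- Filter(function(p) "score" %in% names(p), bundle$predictions)
  if (length(cls) > 0 && "json" %in% format) {
    pts <- do.call(rbind, Map(function(p, key) {
      thr <- sort(unique(p$score), decreasing = TRUE)
      y <- as.integer(p$y_true)
      do.call(rbind, lapply(thr, function(t) {
        pp <- p$score >= t
        data.frame(run = key, threshold = t,
                   tpr = sum(pp & y == 1) / sum(y == 1),
                   fpr = sum(pp & y == 0) / sum(y == 0),
                   precision = sum(pp & y == 1) / sum(pp))
      }))
    }, cls, names(cls)))
    f <- file.path(dir, "roc_pr_points.csv")
    utils::write.csv(pts, f, row.names = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}

#' @export
print.ecgbp_experiment <- function(x, ...) {
  cat(sprintf("<ecgbp_experiment> seed %d, %d subjects, %d result entries\n",
              x$seed, x$n_subjects, length(x$report)))
  invisible(x)
}
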