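#' Analysis run configuration
#'
#' Bundles every tunable of the pipeline so a report can embed the exact
#' configuration that produced it.
#'
#' @param thresholds HU thresholds for quantification/screening.
#' @param fractions slice-selection fractions.
#' @param connectivity Betti connectivity pair (0 set, 1 set).
#' @param b1_cutoff binarization cutoff for the heq_b model.
#' @param cv_k folds for cross-validation.
#' @param seed integer seed for every stochastic stage.
#' @param var_equal `FALSE` for Welch screening t-tests.
#' @param column_map optional column map for cohort ingestion.
#' @return A `run_config` list.
#' @export
run_config <- function(thresholds = .hu_thresholds,
                       fractions = c(0.25, 0.5, 0.75),
                       connectivity = c(8L, 4L),
                       b1_cutoff = 5100,
                       cv_k = 10L,
                       seed = 20190122L,
                       var_equal = FALSE,
                       column_map = NULL) {
  structure(list(thresholds = thresholds, fractions = fractions,
                 connectivity = as.integer(connectivity),
                 b1_cutoff = b1_cutoff, cv_k = as.integer(cv_k),
                 seed = as.integer(seed), var_equal = var_equal,
                 column_map = column_map),
            class = "run_config")
}

#' Run the full risk-model analysis on a cohort
#'
#' Executes the whole statistical pipeline: univariate screening,
#' selection of the analysis threshold (smallest b1 p-value), the four
#' logistic fits (base, laa, heq, heq_b), apparent ROC/AUC per model,
#' pairwise DeLong comparisons, stratified 10-fold cross-validation with
#' pooled out-of-fold AUCs and a DeLong comparison of the
#' cross-validated laa vs heq predictions, and the odds ratio of the
#' binarized b1 term. Any stage failure aborts with the stage name.
#'
#' @param cohort a `cohort_table` (or path to a cohort CSV).
#' @param config a [run_config()].
#' @return A `reproduction_report` list with elements `config`,
#'   `cohort_summary`, `screening`, `best_threshold`, `fits`, `aucs`,
#'   `roc_curves`, `delong`, `cv`, `delong_cv`, `odds_ratio_heq_b`.
#' @export
run_reproduction <- function(cohort, config = run_config()) {
  if (is.character(cohort))
    cohort <- read_cohort(cohort, column_map = config$column_map)
  stopifnot(inherits(cohort, "cohort_table"), inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_heqct("heqct_stage_error", "stage '%s' failed: %s",
                 name, conditionMessage(e)))
  }
  summary_tab <- stage("summary", .cohort_summary(cohort))
  screening <- stage("screening",
                     screen_univariate(cohort, var_equal = config$var_equal))
  best <- stage("threshold_selection",
                select_best_threshold(screening, config$thresholds))
  models <- c("base", "laa", "heq", "heq_b")
  fits <- stage("model_fits", lapply(stats::setNames(models, models),
    function(m) fit_logistic(cohort, m, threshold = best,
                             b1_cutoff = config$b1_cutoff)))
  aucs <- vapply(fits, function(f) roc_auc(f$fitted, f$y), numeric(1))
  rocs <- lapply(fits, function(f) roc_curve(f$fitted, f$y))
  pairs <- list(c("base", "laa"), c("base", "heq"), c("laa", "heq"),
                c("heq", "heq_b"))
  delong <- stage("delong", lapply(pairs, function(p) {
    cmp <- delong_compare(fits[[p[1]]], fits[[p[2]]])
    list(models = p, auc_a = cmp$auc_a, auc_b = cmp$auc_b,
         z = cmp$delong_z, p = cmp$delong_p)
  }))
  cv <- stage("cross_validation", lapply(stats::setNames(models, models),
    function(m) crossvalidate(cohort, m, k = config$cv_k, seed = config$seed,
                              threshold = best, b1_cutoff = config$b1_cutoff)))
  cmp_cv <- stage("delong_cv",
                  delong_compare(cv$laa$oof_prob, cv$heq$oof_prob, cv$laa$y))
  or_b <- stage("odds_ratio", odds_ratio(fits$heq_b, "b1_binary"))
  structure(list(config = config, cohort_summary = summary_tab,
                 screening = screening, best_threshold = best,
                 fits = fits, aucs = aucs, roc_curves = rocs,
                 delong = delong, cv = cv,
                 delong_cv = list(auc_laa = cmp_cv$auc_a,
                                  auc_heq = cmp_cv$auc_b,
                                  z = cmp_cv$delong_z, p = cmp_cv$delong_p),
                 odds_ratio_heq_b = or_b),
            class = "reproduction_report")
}

.cohort_summary <- function(cohort) {
  cont <- c("age", "brinkman_index", "lung_area",
            as.vector(outer(.metric_stems, abs(.hu_thresholds), paste, sep = "_")))
  stats_tab <- data.frame(
    variable = cont,
    mean = vapply(cont, function(v) mean(cohort[[v]], na.rm = TRUE), numeric(1)),
    sd = vapply(cont, function(v) sd(cohort[[v]], na.rm = TRUE), numeric(1)))
  rownames(stats_tab) <- NULL
  list(n = nrow(cohort),
       n_male = sum(cohort$sex == "male"),
       n_cancer = sum(cohort$outcome == "cancer"),
       n_benign = sum(cohort$outcome == "benign"),
       continuous = stats_tab)
}

#' Write a reproduction report as JSON (plus ROC CSVs)
#'
#' @param report a `reproduction_report`.
#' @param path output JSON path; per-model ROC curves are written next
#'   to it as `<path-sans-ext>_roc_<model>.csv`.
#' @export
write_report <- function(report, path) {
  ser <- list(
    config = unclass(report$config),
    cohort_summary = report$cohort_summary,
    screening = report$screening,
    best_threshold = report$best_threshold,
    models = lapply(report$fits, function(f)
      list(model = f$model_name, n_used = f$n_used, aic = f$aic,
           terms = f$terms)),
    aucs = as.list(report$aucs),
    delong = report$delong,
    cv_aucs = lapply(report$cv, function(cv)
      list(k = cv$k, seed = cv$seed, auc = cv$auc)),
    delong_cv = report$delong_cv,
    odds_ratio_heq_b = as.list(report$odds_ratio_heq_b))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  stem <- sub("\\.json$", "", path)
  for (m in names(report$roc_curves))
    write.csv(report$roc_curves[[m]],
              sprintf("%s_roc_%s.csv", stem, m), row.names = FALSE)
  invisible(path)
}

#' @export
print.reproduction_report <- function(x, ...) {
  s <- x$cohort_summary
  cat(sprintf("Cohort: %d patients (%d male), %d cancer / %d benign\n",
              s$n, s$n_male, s$n_cancer, s$n_benign))
  cat(sprintf("Analysis threshold: %g HU\n", x$best_threshold))
  cat("\nModels (apparent / cross-validated AUC, AIC):\n")
  for (m in names(x$fits))
    cat(sprintf("  %-6s AUC %.3f / %.3f   AIC %.1f\n", m,
                x$aucs[[m]], x$cv[[m]]$auc, x$fits[[m]]$aic))
  cat("\nDeLong comparisons (apparent):\n")
  for (d in x$delong)
    cat(sprintf("  %s vs %s: p = %.4g\n", d$models[1], d$models[2], d$p))
  cat(sprintf("\nCross-validated laa vs heq: p = %.4g\n", x$delong_cv$p))
  orb <- x$odds_ratio_heq_b
  cat(sprintf("Odds ratio, binarized b1: %.2f (%.2f-%.2f)\n",
              orb["or"], orb["ci_low"], orb["ci_high"]))
  invisible(x)
}
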