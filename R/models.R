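#' Univariate screening of cohort variables against the outcome
#'
#' Compares every demographic and quantification variable between the
#' cancer and benign groups: continuous variables (age, Brinkman index,
#' lung area, LAA% and b0/b1 at each threshold) by Welch's unequal-
#' variance t-test (Student's as an option), categorical variables (sex,
#' malignant tumor history) by the chi-squared test with Yates continuity
#' correction on the 2x2 table. A variable constant in both groups gets
#' p = 1 with a `degenerate` flag.
#'
#' @param cohort a `cohort_table`.
#' @param var_equal `FALSE` (default) for Welch, `TRUE` for Student.
#' @return A `screening_result` data frame: `variable`, `test`,
#'   `p_value`, `mean_cancer`, `sd_cancer`, `mean_benign`, `sd_benign`
#'   (NA for categorical variables), `degenerate`.
#' @export
screen_univariate <- function(cohort, var_equal = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (anyNA(cohort$outcome))
    stop_heqct("heqct_validation_error", "outcome missing for some rows")
  grp <- cohort$outcome == "cancer"
  cont <- c("age", "brinkman_index", "lung_area",
            as.vector(outer(.metric_stems, abs(.hu_thresholds), paste, sep = "_")))
  cat_vars <- c("sex", "malignant_tumor_history")
  rows <- list()
  for (v in cont) {
    x <- cohort[[v]][grp]; y <- cohort[[v]][!grp]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    degen <- (sd(x) == 0 && sd(y) == 0)
    p <- if (degen) 1 else t.test(x, y, var.equal = var_equal)$p.value
    rows[[v]] <- data.frame(variable = v, test = "welch_t", p_value = p,
                            mean_cancer = mean(x), sd_cancer = sd(x),
                            mean_benign = mean(y), sd_benign = sd(y),
                            degenerate = degen)
  }
  for (v in cat_vars) {
    vals <- cohort[[v]]
    ok <- !is.na(vals)
    if (!any(ok) || length(unique(vals[ok])) < 2L) {
      rows[[v]] <- data.frame(variable = v, test = "chi_squared",
                              p_value = 1, mean_cancer = NA, sd_cancer = NA,
                              mean_benign = NA, sd_benign = NA,
                              degenerate = TRUE)
      next
    }
    tab <- table(vals[ok], grp[ok])
    p <- suppressWarnings(chisq.test(tab, correct = TRUE)$p.value)
    rows[[v]] <- data.frame(variable = v, test = "chi_squared", p_value = p,
                            mean_cancer = NA, sd_cancer = NA,
                            mean_benign = NA, sd_benign = NA,
                            degenerate = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Select the analysis threshold from the screening table
#'
#' Returns the HU threshold whose `b1` p-value is smallest; ties fall
#' back to the smaller LAA% p-value, then to the higher (less negative)
#' threshold.
#'
#' @param screening a `screening_result` from [screen_univariate()].
#' @param thresholds candidate HU thresholds.
#' @return One threshold (numeric HU value).
#' @export
select_best_threshold <- function(screening, thresholds = .hu_thresholds) {
  pick <- function(stem, th) {
    v <- metric_col(stem, th)
    row <- screening[screening$variable == v, ]
    if (nrow(row) != 1L)
      stop_heqct("heqct_schema_error", "screening lacks variable '%s'", v)
    row$p_value
  }
  p_b1 <- vapply(thresholds, function(t) pick("b1", t), numeric(1))
  p_laa <- vapply(thresholds, function(t) pick("laa", t), numeric(1))
  ord <- order(p_b1, p_laa, -thresholds)
  thresholds[ord[1]]
}

#' Binarize the b1 Betti count at an empirical cutoff
#'
#' @param value non-negative b1 count(s).
#' @param cutoff cutoff; returns 1 iff `value > cutoff` (strictly larger).
#' @return 0/1 integer vector.
#' @export
binarize_b1 <- function(value, cutoff = 5100) {
  if (any(value < 0, na.rm = TRUE))
    stop_heqct("heqct_validation_error", "b1 values must be non-negative")
  as.integer(value > cutoff)
}

.model_terms <- function(model_name, threshold, b1_cutoff) {
  base <- c("sex_male", "age", "brinkman_index")
  switch(model_name,
         base  = base,
         laa   = c(base, metric_col("laa", threshold)),
         heq   = c(base, metric_col("b1", threshold)),
         heq_b = c(base, "b1_binary"),
         stop_heqct("heqct_validation_error", "unknown model '%s'", model_name))
}

.model_frame <- function(cohort, model_name, threshold, b1_cutoff) {
  df <- as.data.frame(cohort)
  df$sex_male <- as.integer(df$sex == "male")
  df$y <- as.integer(df$outcome == "cancer")
  if (model_name == "heq_b")
    df$b1_binary <- binarize_b1(df[[metric_col("b1", threshold)]], b1_cutoff)
  terms <- .model_terms(model_name, threshold, b1_cutoff)
  keep <- stats::complete.cases(df[c("y", terms)])
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("fit_logistic[%s]: excluding %d row(s) with missing covariates",
                    model_name, n_dropped))
  list(df = df[keep, , drop = FALSE], terms = terms, n_dropped = n_dropped)
}

#' Fit one of the lung-cancer risk logistic models
#'
#' Maximum-likelihood logistic regression (IRLS; log-likelihood tolerance
#' 1e-8, at most 50 iterations) of cancer vs benign outcome. Model term
#' sets: `base` = sex + age + Brinkman index; `laa` = base + LAA% at the
#' analysis threshold; `heq` = base + b1 at the analysis threshold;
#' `heq_b` = base + b1 binarized at `b1_cutoff`. Sex enters as the
#' male indicator (female = 0, male = 1); covariates are never
#' standardized, so coefficients are on the natural per-unit scale.
#' Rows with missing covariates are excluded with a message.
#'
#' @param cohort a `cohort_table`.
#' @param model_name `"base"`, `"laa"`, `"heq"` or `"heq_b"`.
#' @param threshold analysis HU threshold for the emphysema term.
#' @param b1_cutoff cutoff for the binarized b1 term (heq_b model only).
#' @return A `model_fit` list: `model_name`, `terms` (data frame of
#'   term / coefficient / standard_error / wald_p incl. intercept),
#'   `aic`, `log_lik`, `fitted`, `y`, `n_used`, `n_dropped`, `glm`.
#' @export
fit_logistic <- function(cohort, model_name = c("base", "laa", "heq", "heq_b"),
                         threshold = -880, b1_cutoff = 5100) {
  model_name <- match.arg(model_name)
  mf <- .model_frame(cohort, model_name, threshold, b1_cutoff)
  if (length(unique(mf$df$y)) < 2L)
    stop_heqct("heqct_degenerate_error", "outcome has a single class")
  fml <- stats::as.formula(paste("y ~", paste(mf$terms, collapse = " + ")))
  saturated <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = mf$df,
        control = glm.control(epsilon = 1e-8, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        saturated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop_heqct("heqct_convergence_error", "IRLS did not converge for model '%s'",
               model_name)
  se <- sqrt(diag(vcov(fit)))
  # converged fits pushing probabilities to numerical 0/1 mean the
  # likelihood has no interior maximum for some direction
  saturated <- saturated || any(abs(fit$linear.predictors) > 20)
  if (saturated || any(!is.finite(se))) {
    # name the term with the largest effect on the standardized scale
    sds <- vapply(mf$terms, function(t) sd(mf$df[[t]]), numeric(1))
    bad <- mf$terms[which.max(abs(coef(fit)[mf$terms]) * sds)]
    stop_heqct("heqct_convergence_error",
               "(quasi-)separation suspected for term '%s' in model '%s'",
               bad, model_name)
  }
  z <- coef(fit) / se
  terms_df <- data.frame(term = names(coef(fit)),
                         coefficient = unname(coef(fit)),
                         standard_error = unname(se),
                         wald_p = unname(2 * pnorm(-abs(z))))
  structure(list(model_name = model_name, terms = terms_df,
                 aic = stats::AIC(fit),
                 log_lik = as.numeric(stats::logLik(fit)),
                 fitted = unname(stats::fitted(fit)),
                 y = mf$df$y, patient_id = mf$df$patient_id,
                 n_used = nrow(mf$df), n_dropped = mf$n_dropped,
                 threshold = threshold, b1_cutoff = b1_cutoff, glm = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit '%s': n = %d, AIC = %.1f>\n",
              x$model_name, x$n_used, x$aic))
  df <- x$terms
  df$coefficient <- signif(df$coefficient, 3)
  df$standard_error <- signif(df$standard_error, 3)
  df$wald_p <- signif(df$wald_p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Odds ratio and 95% Wald confidence interval for a model term
#'
#' @param fit a `model_fit`.
#' @param term term name as it appears in `fit$terms$term`.
#' @return Named numeric vector `or`, `ci_low`, `ci_high`
#'   (`exp(coef)` and `exp(coef +/- 1.959964 se)`).
#' @export
odds_ratio <- function(fit, term) {
  row <- fit$terms[fit$terms$term == term, ]
  if (nrow(row) != 1L)
    stop_heqct("heqct_lookup_error", "term '%s' not in model '%s'",
               term, fit$model_name)
  z <- qnorm(0.975)
  c(or = exp(row$coefficient),
    ci_low = exp(row$coefficient - z * row$standard_error),
    ci_high = exp(row$coefficient + z * row$standard_error))
}

.check_binary_outcome <- function(outcomes) {
  y <- if (is.numeric(outcomes)) as.integer(outcomes)
       else as.integer(outcomes == "cancer")
  if (!all(y %in% c(0L, 1L)))
    stop_heqct("heqct_validation_error", "outcomes must be binary")
  if (length(unique(y)) < 2L)
    stop_heqct("heqct_degenerate_error", "need at least one case and one control")
  y
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' AUC = P(score_case > score_control) + 0.5 P(tie), computed from
#' midranks, so exhaustive case-control pair counting is reproduced
#' exactly, ties counted one half.
#'
#' @param probabilities numeric risk scores.
#' @param outcomes binary outcomes (0/1 or benign/cancer), cases = 1.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(probabilities, outcomes) {
  y <- .check_binary_outcome(outcomes)
  stopifnot(length(probabilities) == length(y))
  r <- rank(probabilities, ties.method = "average")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Data frame of (`fpr`, `tpr`) at every distinct score cutoff,
#'   from (0,0) to (1,1).
#' @export
roc_curve <- function(probabilities, outcomes) {
  y <- .check_binary_outcome(outcomes)
  ord <- order(probabilities, decreasing = TRUE)
  y <- y[ord]; p <- probabilities[ord]
  keep <- c(p[-1] != p[-length(p)], TRUE)  # last index of each tie block
  tpr <- cumsum(y) / sum(y)
  fpr <- cumsum(1 - y) / sum(1 - y)
  data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
}

.placements <- function(p, y) {
  # DeLong placement values: for each case, fraction of controls it beats
  # (ties half); and symmetrically for controls.
  cases <- p[y == 1L]; controls <- p[y == 0L]
  m <- length(cases); n <- length(controls)
  cmp <- outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
}

#' DeLong's test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two risk scores evaluated on the same
#' patients, using placement values to estimate the covariance of the two
#' empirical AUCs; the difference is referred to a standard normal
#' (two-sided). Identical scores give z = 0, p = 1.
#'
#' @param scores_a,scores_b numeric risk scores on the same patients
#'   (or `model_fit` objects, whose fitted probabilities are used).
#' @param outcomes binary outcomes shared by both scores; defaults to the
#'   outcome stored in `scores_a` when it is a `model_fit`.
#' @return A `roc_comparison` list: `auc_a`, `auc_b`, `delong_z`,
#'   `delong_p`, `var_diff`, `cov` (2x2 covariance of the AUCs).
#' @export
delong_compare <- function(scores_a, scores_b, outcomes = NULL) {
  if (inherits(scores_a, "model_fit")) {
    if (is.null(outcomes)) outcomes <- scores_a$y
    scores_a <- scores_a$fitted
  }
  if (inherits(scores_b, "model_fit")) scores_b <- scores_b$fitted
  y <- .check_binary_outcome(outcomes)
  if (length(scores_a) != length(y) || length(scores_b) != length(y))
    stop_heqct("heqct_alignment_error",
               "both score vectors must cover the same patients as the outcomes")
  pa <- .placements(scores_a, y)
  pb <- .placements(scores_b, y)
  m <- sum(y == 1L); n <- sum(y == 0L)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, delong_z = z, delong_p = p,
                 var_diff = var_diff, cov = S),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("<roc_comparison: AUC %.4f vs %.4f, z = %.3f, p = %.4g>\n",
              x$auc_a, x$auc_b, x$delong_z, x$delong_p))
  invisible(x)
}

#' DeLong variance of a single AUC
#'
#' @inheritParams roc_auc
#' @return Estimated variance of the empirical AUC.
#' @export
delong_auc_variance <- function(probabilities, outcomes) {
  y <- .check_binary_outcome(outcomes)
  pl <- .placements(probabilities, y)
  stats::var(pl$v10) / sum(y == 1L) + stats::var(pl$v01) / sum(y == 0L)
}

#' Stratified k-fold cross-validation of a risk model
#'
#' Patients are assigned to `k` folds at random, stratified by outcome,
#' from `seed`. Each fold is predicted by a model refitted on the other
#' k-1 folds; the pooled out-of-fold probabilities give a single
#' cross-validated AUC (one patient-level prediction each, as required
#' for a subsequent DeLong comparison of cross-validated models).
#'
#' @inheritParams fit_logistic
#' @param k number of folds (>= 2).
#' @param seed integer seed for fold assignment.
#' @return A `cv_result` list: `k`, `seed`, `fold` (per modelling row),
#'   `oof_prob`, `y`, `auc`.
#' @export
crossvalidate <- function(cohort, model_name, k = 10, seed = 1,
                          threshold = -880, b1_cutoff = 5100) {
  stopifnot(k >= 2)
  mf <- suppressMessages(.model_frame(cohort, model_name, threshold, b1_cutoff))
  df <- mf$df
  y <- df$y
  fold <- integer(nrow(df))
  rng <- local({set.seed(seed); list()})
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  oof <- rep(NA_real_, nrow(df))
  fml <- stats::as.formula(paste("y ~", paste(mf$terms, collapse = " + ")))
  for (f in seq_len(k)) {
    train <- df[fold != f, , drop = FALSE]
    if (length(unique(train$y)) < 2L)
      stop_heqct("heqct_degenerate_error", "fold %d training split has one class", f)
    g <- glm(fml, family = binomial(), data = train,
             control = glm.control(epsilon = 1e-8, maxit = 50))
    oof[fold == f] <- stats::predict(g, newdata = df[fold == f, , drop = FALSE],
                                     type = "response")
  }
  structure(list(k = k, seed = seed, fold = fold, oof_prob = oof, y = y,
                 patient_id = df$patient_id,
                 auc = roc_auc(oof, y)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d-fold (seed %d), pooled AUC = %.4f>\n",
              x$k, x$seed, x$auc))
  invisible(x)
}
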