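make_screening <- function(p_b1, p_laa = c(0.5, 0.5, 0.5)) {
  vars <- c(paste0("b1_", c(950, 910, 880)), paste0("laa_", c(950, 910, 880)))
  out <- data.frame(variable = vars, test = "welch_t",
                    p_value = c(p_b1, p_laa),
                    mean_cancer = NA, sd_cancer = NA,
                    mean_benign = NA, sd_benign = NA, degenerate = FALSE)
  class(out) <- c("screening_result", "data.frame")
  out
}

test_that("univariate screening uses Welch t and Yates chi-squared and flags degenerate variables", {
  co <- generate_cohort(cohort_spec(n_patients = 300, seed = 9))
  sc <- screen_univariate(co)
  expect_true(all(sc$p_value >= 0 & sc$p_value <= 1))
  expect_identical(sort(unique(sc$test)), c("chi_squared", "welch_t"))
  # every screened variable appears exactly once
  expect_identical(anyDuplicated(sc$variable), 0L)
  expect_length(sc$variable, 12 + 2)

  # agreement with the stock tests
  p_age <- t.test(age ~ outcome == "cancer", data = co)$p.value
  expect_equal(sc$p_value[sc$variable == "age"], p_age)
  p_sex <- chisq.test(table(co$sex, co$outcome == "cancer"), correct = TRUE)$p.value
  expect_equal(sc$p_value[sc$variable == "sex"], p_sex)

  # identical groups: p = 1 with degenerate flag
  co2 <- as_cohort(transform(toy_cohort_df(8), lung_area = 5))
  sc2 <- screen_univariate(co2)
  expect_equal(sc2$p_value[sc2$variable == "lung_area"], 1)
  expect_true(sc2$degenerate[sc2$variable == "lung_area"])

  # no-association 2x2 table (balanced 50/50) -> p > 0.999
  df <- toy_cohort_df(200)
  df$sex <- rep(c("male", "female"), 100)
  df$outcome <- rep(c("cancer", "cancer", "benign", "benign"), 50)
  sc3 <- screen_univariate(as_cohort(df))
  expect_gt(sc3$p_value[sc3$variable == "sex"], 0.999)
})

test_that("best threshold minimizes the b1 p-value with laa/HU tie-breaks", {
  expect_equal(select_best_threshold(make_screening(c(0.5, 0.5, 0.01))), -880)
  expect_equal(select_best_threshold(make_screening(c(0.01, 0.5, 0.5))), -950)
  # tie on b1 falls back to the smaller laa p
  expect_equal(select_best_threshold(
    make_screening(c(0.02, 0.02, 0.5), p_laa = c(0.3, 0.1, 0.5))), -910)
  # full tie goes to the higher HU threshold
  expect_equal(select_best_threshold(
    make_screening(c(0.2, 0.2, 0.2), p_laa = c(0.4, 0.4, 0.4))), -880)
  expect_error(select_best_threshold(make_screening(c(0.5, 0.5, 0.01))[-1, ]),
               class = "heqct_schema_error")
})

test_that("b1 binarization is strict at the cutoff", {
  expect_identical(binarize_b1(c(0, 5099, 5100, 5101, 20000)),
                   c(0L, 0L, 0L, 1L, 1L))
  expect_identical(binarize_b1(5100.5), 1L)
  expect_error(binarize_b1(-1), class = "heqct_validation_error")
})

test_that("logistic fits: null covariate, AIC identity, and convergence diagnostics", {
  # balanced toy data, b1 carries no signal
  df <- toy_cohort_df(40, seed = 7)
  # outcome deliberately misaligned with every covariate pattern
  df$outcome <- rep(c("cancer", "cancer", "benign", "benign"), 10)
  set.seed(70)
  df$age <- runif(40, 55, 75); df$brinkman_index <- round(runif(40, 200, 900))
  df$b1_880 <- sample(c(7000, 7400), 40, replace = TRUE)
  co <- as_cohort(df)
  fit <- fit_logistic(co, "heq")
  b1row <- fit$terms[fit$terms$term == "b1_880", ]
  expect_lt(abs(b1row$coefficient * 400), 1)   # no signal at the b1 scale
  expect_gt(b1row$wald_p, 0.5)

  # AIC = 2k - 2 logLik, with logLik recomputed by hand from fitted probs
  ll <- sum(log(ifelse(fit$y == 1, fit$fitted, 1 - fit$fitted)))
  expect_equal(fit$aic, 2 * nrow(fit$terms) - 2 * ll, tolerance = 1e-8)
  expect_equal(fit$log_lik, ll, tolerance = 1e-8)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))

  # perfectly separating covariate triggers a convergence error
  df2 <- toy_cohort_df(40, seed = 8)
  df2$outcome <- rep(c("cancer", "benign"), each = 20)
  df2$b1_880 <- c(rep(9000, 20), rep(1000, 20))
  expect_error(suppressWarnings(fit_logistic(as_cohort(df2), "heq")),
               class = "heqct_convergence_error")
})

test_that("logistic fit recovers generative coefficients within 2 SE at n = 5000", {
  spec <- cohort_spec(n_patients = 5000, seed = 314,
                      coef = c(intercept = -2.2, sex_male = -0.44,
                               age = 0.026, brinkman_index = 0.000294,
                               b1 = 0.000104))
  co <- generate_cohort(spec)
  truth <- attr(co, "truth")$coef
  fit <- fit_logistic(co, "heq")
  est <- fit$terms
  map <- c("(Intercept)" = "intercept", sex_male = "sex_male", age = "age",
           brinkman_index = "brinkman_index", b1_880 = "b1")
  for (term in names(map)) {
    row <- est[est$term == term, ]
    expect_lt(abs(row$coefficient - truth[[map[[term]]]]),
              2 * row$standard_error,
              label = sprintf("|bias| of %s", term))
  }
})

test_that("odds ratios follow the closed form exp(coef +/- 1.96 SE)", {
  fit <- list(model_name = "toy",
              terms = data.frame(term = c("a", "b"),
                                 coefficient = c(0, 0.825),
                                 standard_error = c(0.1, 0.25),
                                 wald_p = c(1, 0.001)))
  class(fit) <- "model_fit"
  or_a <- odds_ratio(fit, "a")
  expect_equal(unname(or_a["or"]), 1)
  expect_equal(unname(or_a["ci_low"]), exp(-qnorm(0.975) * 0.1), tolerance = 1e-8)
  expect_equal(round(unname(or_a[c("ci_low", "ci_high")]), 3), c(0.822, 1.217))
  expect_equal(unname(odds_ratio(fit, "b")["or"]), exp(0.825))
  expect_equal(round(unname(odds_ratio(fit, "b")["or"]), 3), 2.282)
  expect_error(odds_ratio(fit, "nope"), class = "heqct_lookup_error")
})

test_that("AUC: closed cases, the 6-point worked example, and the pair-counting oracle", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(roc_auc(1:6, c(0, 0, 1, 0, 1, 1)), 8 / 9)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), class = "heqct_degenerate_error")

  set.seed(123)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # plenty of ties
    expect_equal(roc_auc(s, y), auc_oracle(s, y))
  }
})

test_that("ROC curves start at (0,0), end at (1,1), and match pROC's AUC", {
  set.seed(5)
  y <- rbinom(80, 1, 0.5); s <- rnorm(80) + y
  rc <- roc_curve(s, y)
  expect_equal(unlist(rc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(rc[nrow(rc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  p_auc <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(roc_auc(s, y), p_auc, tolerance = 1e-12)
})

test_that("DeLong comparison: self-test is null, and z/p match pROC", {
  set.seed(21)
  y <- rbinom(120, 1, 0.45)
  a <- rnorm(120) + 0.8 * y
  b <- rnorm(120) + 0.5 * y
  self <- delong_compare(a, a, y)
  expect_identical(self$delong_z, 0)
  expect_identical(self$delong_p, 1)

  cmp <- delong_compare(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE), method = "delong")
  expect_equal(abs(cmp$delong_z), abs(as.numeric(ref$statistic)), tolerance = 1e-8)
  expect_equal(cmp$delong_p, as.numeric(ref$p.value), tolerance = 1e-8)
  expect_equal(cmp$auc_a, roc_auc(a, y))

  expect_error(delong_compare(a[-1], b, y), class = "heqct_alignment_error")

  # single-AUC DeLong variance matches pROC's
  expect_equal(delong_auc_variance(a, y),
               as.numeric(pROC::var(pROC::roc(y, a, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("DeLong variance agrees with bootstrap variance within 15%", {
  set.seed(31)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  s <- rnorm(n) + 0.6 * y
  v_delong <- delong_auc_variance(s, y)
  boots <- replicate(1000, {
    i <- sample.int(n, replace = TRUE)
    if (length(unique(y[i])) < 2) NA_real_ else roc_auc(s[i], y[i])
  })
  v_boot <- var(boots, na.rm = TRUE)
  expect_lt(abs(v_delong - v_boot) / v_boot, 0.15)
})

test_that("cross-validation is stratified, reproducible, and honest", {
  co <- generate_cohort(cohort_spec(n_patients = 400, seed = 55))
  cv1 <- crossvalidate(co, "heq", k = 10, seed = 99)
  cv2 <- crossvalidate(co, "heq", k = 10, seed = 99)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$auc, cv2$auc)
  expect_false(identical(cv1$fold, crossvalidate(co, "heq", k = 10, seed = 100)$fold))

  # folds partition the rows and stratify the outcome
  expect_identical(sort(unique(cv1$fold)), 1:10)
  expect_true(all(abs(tapply(cv1$y, cv1$fold, sum) - sum(cv1$y) / 10) <= 1))
  expect_false(anyNA(cv1$oof_prob))

  # perfectly separable data: pooled out-of-fold AUC is 1
  df <- toy_cohort_df(60, seed = 3)
  df$outcome <- rep(c("cancer", "benign"), each = 30)
  df$age <- c(rnorm(30, 75, 1), rnorm(30, 45, 1))
  cv_sep <- suppressWarnings(crossvalidate(as_cohort(df), "base", k = 5, seed = 1))
  expect_equal(cv_sep$auc, 1)
})

test_that("cross-validated AUC does not beat apparent AUC on average", {
  deltas <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_spec(n_patients = 250, seed = 1000 + s))
    fit <- fit_logistic(co, "heq")
    apparent <- roc_auc(fit$fitted, fit$y)
    apparent - crossvalidate(co, "heq", k = 10, seed = s)$auc
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})
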