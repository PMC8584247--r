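#' ROC analysis of a single marker
#'
#' AUC by the rank (Mann-Whitney) formulation with tie correction and a 95%
#' confidence interval from the DeLong variance estimator (both via
#' \pkg{pROC}). Orientation is chosen so that AUC >= 0.5; which class scored
#' higher is recorded.
#'
#' @param values Numeric marker values.
#' @param labels Two-level class labels aligned with `values`.
#' @param ci_method `"delong"` (default) or `"bootstrap"` (2000 resamples;
#'   seed the session for reproducibility).
#' @return List of class `roc_curve`: `auc`, `ci` (lower, upper),
#'   `higher_in` (class with the larger median score under the chosen
#'   orientation), `n` per class.
#' @export
roc_single <- function(values, labels, ci_method = c("delong", "bootstrap")) {
  ci_method <- match.arg(ci_method)
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2L) stop("labels must have exactly two classes")
  ## fit both orientations and keep the one with AUC >= 0.5
  r <- pROC::roc(response = factor(labels, levels = lev), predictor = values,
                 levels = lev, direction = "<", quiet = TRUE)
  if (as.numeric(pROC::auc(r)) < 0.5) {
    r <- pROC::roc(response = factor(labels, levels = lev),
                   predictor = values, levels = lev, direction = ">",
                   quiet = TRUE)
  }
  ci <- suppressWarnings(
    pROC::ci.auc(r, method = if (ci_method == "delong") "delong" else
      "bootstrap", boot.n = 2000))
  higher <- if (r$direction == "<") lev[2] else lev[1]
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci = c(lower = as.numeric(ci[1]), upper = as.numeric(ci[3])),
                 higher_in = higher,
                 n = table(labels)),
            class = "roc_curve")
}

## ROC of a score with a FIXED orientation (higher score = second class in
## sorted label order). Used for the logistic panel score, whose direction
## is defined by the fit: flipping a cross-validated score would bias a
## null panel away from AUC 0.5.
roc_fixed_direction <- function(values, labels) {
  lev <- sort(unique(as.character(labels)))
  r <- pROC::roc(response = factor(labels, levels = lev), predictor = values,
                 levels = lev, direction = "<", quiet = TRUE)
  ci <- suppressWarnings(pROC::ci.auc(r, method = "delong"))
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci = c(lower = as.numeric(ci[1]), upper = as.numeric(ci[3])),
                 higher_in = lev[2],
                 n = table(labels)),
            class = "roc_curve")
}

## Logistic combining score on standardized columns; falls back to a
## ridge-stabilized fit when the groups are (quasi-)separable.
fit_logistic_score <- function(x, y01) {
  x <- scale(x)
  x[is.nan(x)] <- 0  # constant columns carry no information
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, x), y01, family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning")
  )
  separated <- !fit$converged || any(abs(fit$coefficients[-1]) > 15)
  if (separated) {
    rf <- glmnet::glmnet(x, y01, family = "binomial", alpha = 0,
                         lambda = 0.01, standardize = FALSE)
    coefs <- as.numeric(stats::coef(rf))
  } else {
    coefs <- fit$coefficients
  }
  list(coefficients = coefs, ridged = separated,
       score = as.numeric(cbind(1, x) %*% coefs))
}

#' ROC analysis of a combined marker panel
#'
#' Fits a logistic combining score on the standardized expression of the
#' panel members and evaluates the ROC of that score. The default is the
#' in-sample (apparent) AUC; `cv_folds > 1` instead scores each sample from
#' a model fit without its fold (stratified k-fold cross-validation, seeded
#' by the session RNG). When the classes are perfectly separable the
#' logistic fit is ridge-stabilized and flagged.
#'
#' @param mat Matrix samples x markers (no missing values).
#' @param labels Two-level class labels per sample.
#' @param cv_folds 0 or 1 for in-sample scoring; k >= 2 for k-fold CV.
#' @return List of class `panel_roc`: `roc` (a `roc_curve` on the combining
#'   score), `coefficients`, `ridged`, `cv_folds`, `members`.
#' @export
combined_panel_roc <- function(mat, labels, cv_folds = 0L) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop("panel matrix must have no missing values")
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2L) stop("labels must have exactly two classes")
  y01 <- as.integer(labels == lev[2])
  if (min(table(labels)) < 2L) stop("need >= 2 samples per class")
  if (cv_folds >= 2L) {
    folds <- integer(length(y01))
    for (cl in 0:1) {
      idx <- which(y01 == cl)
      folds[idx] <- sample(rep(seq_len(cv_folds), length.out = length(idx)))
    }
    score <- numeric(length(y01))
    ridged <- FALSE
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      fit <- fit_logistic_score(mat[tr, , drop = FALSE], y01[tr])
      ridged <- ridged || fit$ridged
      mu <- colMeans(mat[tr, , drop = FALSE])
      sd_ <- apply(mat[tr, , drop = FALSE], 2, stats::sd)
      sd_[sd_ == 0] <- 1
      xs <- sweep(sweep(mat[!tr, , drop = FALSE], 2, mu, `-`), 2, sd_, `/`)
      score[!tr] <- as.numeric(cbind(1, xs) %*% fit$coefficients)
    }
    coefs <- NULL
  } else {
    fit <- fit_logistic_score(mat, y01)
    score <- fit$score
    ridged <- fit$ridged
    coefs <- fit$coefficients
  }
  structure(list(roc = roc_fixed_direction(score, labels),
                 coefficients = coefs, ridged = ridged,
                 cv_folds = if (cv_folds >= 2L) cv_folds else 0L,
                 members = colnames(mat)),
            class = "panel_roc")
}

#' Association of miRNA expression with a continuous covariate
#'
#' Univariable linear regression with the miRNA log2 values as outcome and
#' the covariate as regressor.
#'
#' @param mirna_values Numeric outcome vector (log2 expression).
#' @param covariate Numeric regressor (e.g. age, tumor size); constant
#'   covariates are an error. Missing covariate values drop the sample.
#' @return `data.frame`: `model`, `effect` (slope), `intercept`, `p`, `n`.
#' @export
associate_continuous <- function(mirna_values, covariate) {
  ok <- is.finite(mirna_values) & is.finite(covariate)
  x <- covariate[ok]; y <- mirna_values[ok]
  if (length(x) < 3L) stop("need >= 3 complete samples")
  if (stats::sd(x) == 0) stop("constant covariate")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  data.frame(model = "linear", effect = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             p = sm$coefficients[2, 4], n = length(x),
             stringsAsFactors = FALSE)
}

#' Association of miRNA expression with a binary covariate
#'
#' Reports both an unpaired Student t-test between the two levels and the
#' Wald p-value of the covariate coefficient in a logistic regression of the
#' flag on expression.
#'
#' @param mirna_values Numeric expression vector.
#' @param flag Two-level factor/vector; missing values drop the sample.
#' @return `data.frame` with one row per model (`t_test`, `logistic`):
#'   `effect` (mean difference level2 - level1, resp. log-odds slope), `p`.
#' @export
associate_binary <- function(mirna_values, flag) {
  ok <- is.finite(mirna_values) & !is.na(flag)
  y <- mirna_values[ok]; f <- as.character(flag[ok])
  lev <- sort(unique(f))
  if (length(lev) != 2L) stop("flag must have exactly two observed levels")
  if (min(table(f)) < 2L) stop("each level needs >= 2 samples")
  tt <- safe_t_test(y[f == lev[2]], y[f == lev[1]])
  lfit <- suppressWarnings(stats::glm(factor(f, levels = lev) ~ y,
                                      family = stats::binomial()))
  sm <- summary(lfit)
  data.frame(model = c("t_test", "logistic"),
             effect = c(tt$estimate, unname(stats::coef(lfit)[2])),
             p = c(tt$p.value, sm$coefficients[2, 4]),
             stringsAsFactors = FALSE)
}

#' Group comparison of clinical variables
#'
#' For each variable: categorical variables are tested with the chi-squared
#' test, or Fisher's exact test when any expected cell count is below 5;
#' continuous variables with a two-sided t-test (Wilcoxon-Mann-Whitney by
#' flag). Missing values are dropped per variable; all-missing variables are
#' skipped with a warning.
#'
#' @param clinical `data.frame` of clinical variables (rows = samples).
#' @param groups Group label per row of `clinical` (two levels).
#' @param types Named character vector mapping variable name to
#'   `"categorical"` or `"continuous"`; variables not listed are skipped.
#' @param continuous_test `"t"` (default) or `"wilcoxon"`.
#' @return `data.frame`: `variable`, `test`, `p`, `n_used`.
#' @export
compare_clinical_tables <- function(clinical, groups, types,
                                    continuous_test = c("t", "wilcoxon")) {
  continuous_test <- match.arg(continuous_test)
  out <- list()
  for (v in names(types)) {
    x <- clinical[[v]]
    ok <- !is.na(x) & !is.na(groups)
    if (!any(ok)) {
      warning("variable ", v, " is all-missing; skipped")
      next
    }
    g <- factor(groups[ok])
    if (types[[v]] == "categorical") {
      tab <- table(factor(x[ok]), g)
      if (nrow(tab) < 2L || min(dim(tab)) < 2L) {
        res <- list(test = "fisher", p = 1)  # degenerate single-level table
      } else {
        expected <- suppressWarnings(stats::chisq.test(tab)$expected)
        if (any(expected < 5)) {
          res <- list(test = "fisher", p = stats::fisher.test(tab)$p.value)
        } else {
          res <- list(test = "chisq",
                      p = stats::chisq.test(tab, correct = FALSE)$p.value)
        }
      }
    } else {
      xs <- split(as.numeric(x[ok]), g)
      if (continuous_test == "t") {
        res <- list(test = "t", p = safe_t_test(xs[[1]], xs[[2]])$p.value)
      } else {
        res <- list(test = "wilcoxon",
                    p = suppressWarnings(
                      stats::wilcox.test(xs[[1]], xs[[2]])$p.value))
      }
    }
    out[[length(out) + 1L]] <- data.frame(variable = v, test = res$test,
                                          p = res$p, n_used = sum(ok),
                                          stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
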