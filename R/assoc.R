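#' Association results
#'
#' `assoc_result` objects hold one covariate-adjusted association between a
#' genetic score and an outcome: the point estimate on the estimation scale
#' (per ms of score), its standard error, Wald 95% confidence interval,
#' two-sided p-value, sample size, scale label and significance flag per
#' the reporting convention (p < 0.01 significant, p < 0.05 suggestive).
#'
#' @param beta,se Estimate and standard error.
#' @param n Sample size.
#' @param outcome_label Free-text outcome name.
#' @param scale One of `"per-ms"`, `"per-5ms"`, `"per-quintile"`.
#' @param family `"gaussian"` or `"binomial"` (log-odds estimate).
#' @return An `assoc_result` object.
#' @keywords internal
new_assoc_result <- function(beta, se, n, outcome_label = "outcome",
                             scale = "per-ms", family = "binomial") {
  beta <- unname(beta)
  se <- unname(se)
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(beta = beta, se = se,
                 ci_low = beta - 1.96 * se,
                 ci_high = beta + 1.96 * se,
                 z = z, p = p, n = n,
                 outcome_label = outcome_label,
                 scale = scale, family = family,
                 significance = significance_flag(p)),
            class = "assoc_result")
}

#' Significance flag per the reporting convention
#'
#' Two-tailed p-values below 0.01 are flagged `"significant"`, below 0.05
#' `"suggestive"`, otherwise `"ns"`. Flags annotate output; they never
#' alter estimates.
#'
#' @param p Two-sided p-value(s).
#' @return Character vector of flags.
#' @export
significance_flag <- function(p) {
  ifelse(p < 0.01, "significant", ifelse(p < 0.05, "suggestive", "ns"))
}

#' @export
print.assoc_result <- function(x, ...) {
  est <- if (x$family == "binomial")
    sprintf("OR %.4f (95%% CI %.4f-%.4f)",
            exp(x$beta), exp(x$ci_low), exp(x$ci_high))
  else
    sprintf("beta %.4f (95%% CI %.4f to %.4f)", x$beta, x$ci_low, x$ci_high)
  cat(sprintf("%s ~ score [%s]: %s, p = %.3g (%s), n = %d\n",
              x$outcome_label, x$scale, est, x$p, x$significance, x$n))
  invisible(x)
}

#' @export
coef.assoc_result <- function(object, ...) object$beta

#' @export
confint.assoc_result <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(object$beta - z * object$se, object$beta + z * object$se)
}

covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  m <- as.matrix(as.data.frame(covariates))
  stopifnot(nrow(m) == n)
  storage.mode(m) <- "double"
  m
}

check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
}

#' Linear association between a genetic score and a continuous outcome
#'
#' Ordinary least squares of the phenotype on the score with covariate
#' adjustment (the convention being sex, genotyping array and principal
#' components of ancestry). Serves the score-to-ECG-interval first-stage
#' display and any continuous downstream outcome such as indexed left
#' atrial volume.
#'
#' @param score A `genetic_score` or numeric vector.
#' @param phenotype Continuous outcome vector.
#' @param covariates Optional data frame/matrix of adjustment covariates.
#' @param outcome_label Label carried into the result.
#' @return An `assoc_result` (Gaussian family), per ms of score.
#' @export
linear_assoc <- function(score, phenotype, covariates = NULL,
                         outcome_label = "phenotype") {
  x <- score_values(score)
  n <- length(x)
  stopifnot(length(phenotype) == n)
  C <- covariate_matrix(covariates, n)
  X <- cbind(`(Intercept)` = 1, score = x, C)
  check_full_rank(X)
  fit <- stats::lm.fit(X, phenotype)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / fit$df.residual
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  new_assoc_result(fit$coefficients["score"], se, n,
                   outcome_label, scale = "per-ms", family = "gaussian")
}

#' Logistic association between a genetic score and a binary outcome
#'
#' Maximum-likelihood logistic regression of the outcome on the score with
#' covariate adjustment; the estimate is the log odds ratio per ms of
#' score. Errors on non-convergence and on detected separation.
#'
#' @inheritParams linear_assoc
#' @param outcome Binary 0/1 outcome vector with both classes present.
#' @param extra Optional extra columns added to the design after the score
#'   (used for second-score adjustment).
#' @return An `assoc_result` (binomial family), per ms of score.
#' @export
logistic_assoc <- function(score, outcome, covariates = NULL,
                           outcome_label = "outcome", extra = NULL) {
  x <- score_values(score)
  n <- length(x)
  stopifnot(length(outcome) == n, all(outcome %in% 0:1))
  if (length(unique(outcome)) < 2L)
    stop("both outcome classes must be present")
  C <- covariate_matrix(covariates, n)
  X <- cbind(`(Intercept)` = 1, score = x, extra, C)
  check_full_rank(X)
  fit <- stats::glm.fit(X, outcome, family = stats::binomial())
  if (!fit$converged) stop("logistic fit did not converge")
  mu <- fit$fitted.values
  if (any(mu < 1e-10 | mu > 1 - 1e-10) && max(abs(fit$coefficients)) > 10)
    stop("separation detected: fitted probabilities of 0/1 with ",
         "diverging coefficients")
  w <- fit$weights
  XtWXinv <- chol2inv(chol(crossprod(X * sqrt(w))))
  se <- sqrt(XtWXinv[2, 2])
  new_assoc_result(fit$coefficients["score"], se, n,
                   outcome_label, scale = "per-ms", family = "binomial")
}

#' Rescale a per-ms association to per 5 ms
#'
#' Effects of ECG genetic scores on arrhythmia risk are reported per 5 ms
#' difference in score: beta and SE are multiplied by 5 (so the odds ratio
#' becomes `exp(5 * beta_per_ms)`); the p-value is unchanged. Guarded
#' against double scaling via the `scale` field.
#'
#' @param result An `assoc_result` or `mr_estimate` on the per-ms scale.
#' @return The same object rescaled, `scale = "per-5ms"`.
#' @export
scale_per_5ms <- function(result) UseMethod("scale_per_5ms")

#' @export
scale_per_5ms.assoc_result <- function(result) {
  if (!identical(result$scale, "per-ms"))
    stop("result is on scale '", result$scale, "', not 'per-ms'")
  out <- new_assoc_result(result$beta * 5, result$se * 5, result$n,
                          result$outcome_label, scale = "per-5ms",
                          family = result$family)
  out
}

#' Association of a score adjusted for a second score
#'
#' Logistic regression including both scores (plus covariates); reports
#' the primary score's effect. Used to test whether the PR-interval effect
#' survives adjustment for the P-wave-duration score.
#'
#' @param score Primary `genetic_score`.
#' @param adjust_score Second score entered as a covariate.
#' @param outcome Binary outcome vector.
#' @param covariates Optional covariates.
#' @param outcome_label Label for the result.
#' @return An `assoc_result` for the primary score, per ms.
#' @export
adjusted_for_second_score <- function(score, adjust_score, outcome,
                                      covariates = NULL,
                                      outcome_label = "outcome") {
  x1 <- score_values(score)
  x2 <- score_values(adjust_score)
  r <- stats::cor(x1, x2)
  if (abs(r) > 0.99)
    stop(sprintf("scores are near-collinear (|r| = %.3f > 0.99)", abs(r)))
  logistic_assoc(score, outcome, covariates, outcome_label,
                 extra = cbind(adjust_score = x2))
}

#' Two-sided Wald p-value from an odds ratio and its 95% CI
#'
#' Inverts the Wald confidence-interval convention: the standard error is
#' recovered as `(log ci_high - log ci_low) / (2 * 1.96)` and the p-value
#' as the two-sided normal tail of `log(or) / se`. Used to check that
#' reported OR/CI/p triplets are internally consistent.
#'
#' @param or Odds ratio.
#' @param ci_low,ci_high 95% confidence bounds, `0 < ci_low <= or <= ci_high`.
#' @return Two-sided p-value.
#' @export
wald_p_from_or_ci <- function(or, ci_low, ci_high) {
  stopifnot(ci_low > 0, ci_low <= or, or <= ci_high)
  if (ci_low == ci_high) stop("degenerate confidence interval")
  se <- (log(ci_high) - log(ci_low)) / (2 * 1.96)
  z <- log(or) / se
  2 * stats::pnorm(-abs(z))
}
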