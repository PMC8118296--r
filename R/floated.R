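#' Quintile contrasts with floated variances
#'
#' Fits a logistic model with indicator terms for score quintiles 2-5
#' (bottom quintile as the fitting reference, plus covariates) and
#' re-expresses the four log odds ratios with *floated variances*: each
#' group, including the reference, receives its own variance \eqn{\lambda_g}
#' such that for any pair of groups \eqn{(i, j)},
#' \eqn{\lambda_i + \lambda_j \approx Var(b_i - b_j)}. This lets a display
#' attach a confidence interval to every group without privileging an
#' arbitrary reference, and any pairwise contrast can be reconstructed.
#'
#' The reference-group variance \eqn{\lambda_0} is chosen by a
#' one-dimensional minimisation of the maximum relative error of
#' \eqn{\lambda_i + \lambda_j} against the true contrast variance over all
#' pairs; the non-reference variances are then
#' \eqn{\lambda_i = Var(b_i) - \lambda_0} (floored just above zero).
#' Contrasts against the reference are reproduced exactly by construction;
#' the attained maximum relative error over all pairs is reported on every
#' call. With only two groups the representation is exactly identified.
#'
#' @param score A `genetic_score` or numeric vector.
#' @param outcome Binary 0/1 outcome vector.
#' @param covariates Optional data frame/matrix of adjustment covariates.
#' @param quintiles Optional precomputed group labels from
#'   [assign_quintiles()]; by default quintiles are computed with the
#'   non-case individuals as the reference subset.
#' @param n_groups Number of score groups (5 for quintiles).
#' @return A `floated_risk` data frame with one row per group: `group`,
#'   `log_or` (relative to the bottom group), `floated_variance`,
#'   `or`, `ci_low`, `ci_high` (floated 95% bounds), `n`, `cases`;
#'   attributes `max_rel_error` (worst pairwise contrast-variance error)
#'   and `vcov` (covariance matrix of the non-reference log-ORs).
#' @export
quintile_contrasts <- function(score, outcome, covariates = NULL,
                               quintiles = NULL, n_groups = 5L) {
  x <- score_values(score)
  n <- length(x)
  stopifnot(length(outcome) == n, all(outcome %in% 0:1))
  if (is.null(quintiles))
    quintiles <- assign_quintiles(score, reference = outcome == 0L)
  q <- as.integer(quintiles)
  stopifnot(length(q) == n, all(q >= 1L), all(q <= n_groups))
  # indicator design: groups 2..n_groups, bottom group is fitting reference
  D <- vapply(2:n_groups, function(k) as.numeric(q == k), numeric(n))
  colnames(D) <- paste0("Q", 2:n_groups)
  C <- covariate_matrix(covariates, n)
  X <- cbind(`(Intercept)` = 1, D, C)
  check_full_rank(X)
  fit <- stats::glm.fit(X, outcome, family = stats::binomial())
  if (!fit$converged) stop("logistic fit did not converge")
  w <- fit$weights
  Vfull <- chol2inv(chol(crossprod(X * sqrt(w))))
  idx <- 1L + seq_len(n_groups - 1L)  # positions of Q2..Qk
  V <- Vfull[idx, idx, drop = FALSE]
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("covariance matrix of the group log-ORs is not positive definite")
  b <- fit$coefficients[idx]
  fl <- float_variances(V)
  lam <- c(fl$lambda0, fl$lambda)
  log_or <- c(0, b)
  out <- data.frame(
    group = seq_len(n_groups),
    log_or = log_or,
    floated_variance = lam,
    or = exp(log_or),
    ci_low = exp(log_or - 1.96 * sqrt(lam)),
    ci_high = exp(log_or + 1.96 * sqrt(lam)),
    n = as.integer(tabulate(q, n_groups)),
    cases = as.integer(tabulate(q[outcome == 1L], n_groups))
  )
  structure(out, max_rel_error = fl$max_rel_error, vcov = V,
            class = c("floated_risk", "data.frame"))
}

# Floated variances from the covariance matrix V of the non-reference
# log-ORs (reference coefficient fixed at 0). Contrasts with the
# reference have Var(b_i) = V_ii = lambda0 + (V_ii - lambda0) exactly for
# any lambda0, so only non-reference pairs constrain the choice:
# lambda_i + lambda_j - Var(b_i - b_j) = 2 (V_ij - lambda0). lambda0 is
# chosen to minimise the worst relative error over those pairs.
float_variances <- function(V) {
  k <- ncol(V)
  dV <- diag(V)
  if (k == 1L) {
    # two groups: exactly identified, split the contrast variance
    lam0 <- dV / 2
    return(list(lambda0 = lam0, lambda = dV - lam0, max_rel_error = 0))
  }
  pairs <- utils::combn(k, 2)
  cvar <- dV[pairs[1, ]] + dV[pairs[2, ]] -
    2 * V[cbind(pairs[1, ], pairs[2, ])]
  offd <- V[cbind(pairs[1, ], pairs[2, ])]
  obj <- function(l0) max(abs(2 * (offd - l0)) / cvar)
  floor_ <- 1e-12
  upper <- min(dV) - floor_
  opt <- stats::optimize(obj, lower = 0, upper = max(upper, floor_))
  lam0 <- opt$minimum
  lam <- pmax(dV - lam0, floor_)
  # attained error over all pairs incl. reference pairs (those are exact)
  err <- obj(lam0)
  list(lambda0 = lam0, lambda = lam, max_rel_error = err)
}

#' @export
print.floated_risk <- function(x, ...) {
  cat("Group risks with floated variances (bottom group = baseline)\n")
  df <- data.frame(group = x$group,
                   OR = sprintf("%.3f", x$or),
                   `95% CI` = sprintf("%.3f-%.3f", x$ci_low, x$ci_high),
                   n = x$n, cases = x$cases, check.names = FALSE)
  print(df, row.names = FALSE)
  cat(sprintf("max relative contrast-variance error: %.2f%%\n",
              100 * attr(x, "max_rel_error")))
  invisible(x)
}

#' Reconstruct a pairwise contrast from floated variances
#'
#' Forms the log odds ratio of group `i` versus group `j` with standard
#' error `sqrt(lambda_i + lambda_j)`, the operation floated variances are
#' designed to support for arbitrary pairs.
#'
#' @param floated A `floated_risk` object.
#' @param i,j Group labels to contrast (effect of `i` relative to `j`).
#' @return An `assoc_result` on the per-quintile scale.
#' @export
floated_contrast <- function(floated, i, j = 1L) {
  stopifnot(inherits(floated, "floated_risk"))
  ri <- match(i, floated$group)
  rj <- match(j, floated$group)
  stopifnot(!is.na(ri), !is.na(rj), ri != rj)
  beta <- floated$log_or[ri] - floated$log_or[rj]
  se <- sqrt(floated$floated_variance[ri] + floated$floated_variance[rj])
  new_assoc_result(beta, se, sum(floated$n[c(ri, rj)]),
                   sprintf("group %s vs %s", i, j),
                   scale = "per-quintile", family = "binomial")
}

#' Display table for group-level score/interval figures
#'
#' Publication figures show each quintile's mean genetic score with a
#' constant added: the population mean of the measured interval excluding
#' the genetic contribution, so the displayed values sit on the familiar
#' ms scale of the interval itself. This helper produces that table;
#' the constant affects display only, never any estimate.
#'
#' @param score A `genetic_score` or numeric vector.
#' @param quintiles Labels from [assign_quintiles()].
#' @param display_constant Additive constant in ms (e.g. 93.5 for a PR
#'   interval score).
#' @return Data frame: `group`, `mean_score`, `displayed_value`.
#' @export
quintile_display <- function(score, quintiles, display_constant = 0) {
  x <- score_values(score)
  g <- as.integer(quintiles)
  mu <- tapply(x, g, mean)
  data.frame(group = as.integer(names(mu)),
             mean_score = as.numeric(mu),
             displayed_value = as.numeric(mu) + display_constant)
}
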