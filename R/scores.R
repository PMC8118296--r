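#' Build a weighted genetic score
#'
#' Per-individual weighted sum of effect-allele dosages,
#' `score_i = sum_j w_j g_ij`, the allele-score instrument for an ECG
#' interval. Weights are the published per-allele effects in milliseconds,
#' so the score itself is in ms. Missing dosages, if any, are mean-imputed
#' per variant before summing (preserves the score scale).
#'
#' @param genotypes Dosage matrix with variant ids as column names.
#' @param weights Named numeric vector, variant id -> per-allele weight (ms).
#' @return A `genetic_score` object: list with `values` (numeric vector),
#'   `weights` and `n_variants`.
#' @export
build_score <- function(genotypes, weights) {
  stopifnot(is.matrix(genotypes), is.numeric(weights),
            !is.null(names(weights)))
  missing <- setdiff(names(weights), colnames(genotypes))
  if (length(missing))
    stop("weights refer to variant(s) absent from the genotype matrix: ",
         paste(missing, collapse = ", "))
  g <- genotypes[, names(weights), drop = FALSE]
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- mu[j]
  }
  structure(list(values = drop(g %*% weights),
                 weights = weights,
                 n_variants = length(weights)),
            class = "genetic_score")
}

#' @export
print.genetic_score <- function(x, ...) {
  cat(sprintf("Genetic score: %d variants, n = %d, mean %.2f ms, sd %.2f ms\n",
              x$n_variants, length(x$values),
              mean(x$values), stats::sd(x$values)))
  invisible(x)
}

score_values <- function(score) {
  if (inherits(score, "genetic_score")) score$values else as.numeric(score)
}

#' Assign score quintiles from a reference subset
#'
#' Quintile cut-points are computed within a designated reference subset
#' (conventionally the non-case individuals, to avoid the case mix shifting
#' the grid) and then applied to the full cohort. Within the reference
#' subset group sizes are equal to within one individual; ties spanning a
#' cut-point are broken by stable input order.
#'
#' @param score A `genetic_score` or numeric vector.
#' @param reference Logical vector marking the reference subset (default:
#'   everyone).
#' @return Integer vector of group labels 1 (lowest fifth) to 5 (highest),
#'   with the four cut-points as attribute `cutpoints`.
#' @export
assign_quintiles <- function(score, reference = NULL) {
  x <- score_values(score)
  n <- length(x)
  if (is.null(reference)) reference <- rep(TRUE, n)
  stopifnot(is.logical(reference), length(reference) == n)
  xr <- x[reference]
  if (length(unique(xr)) < 5L)
    stop("cannot form quintiles: fewer than 5 distinct score values ",
         "in the reference subset")
  r <- rank(xr, ties.method = "first")  # stable: ties by input order
  gr <- ceiling(5 * r / length(xr))
  cuts <- vapply(1:4, function(k) max(xr[gr == k]), numeric(1))
  g <- integer(n)
  g[reference] <- gr
  out <- !reference
  # ties exactly at a cut-point fall in the lower group, matching max-in-group
  g[out] <- 1L + vapply(x[out], function(v) sum(v > cuts), integer(1))
  structure(g, cutpoints = cuts)
}

#' Variance in a phenotype explained by a genetic score
#'
#' R-squared from the simple linear regression of the phenotype on the
#' score; equal to the squared Pearson correlation.
#'
#' @param score A `genetic_score` or numeric vector.
#' @param phenotype Paired phenotype vector, same trait as the score.
#' @return R-squared in \[0, 1\].
#' @export
variance_explained <- function(score, phenotype) {
  x <- score_values(score)
  stopifnot(length(x) == length(phenotype))
  if (stats::var(x) == 0) stop("score has zero variance")
  stats::cor(x, phenotype)^2
}

#' Instrument-strength F statistic
#'
#' F statistic of the one-regressor (allele-score) first-stage regression,
#' `F = r2 (n - 2) / (1 - r2)`. Values above 10 are conventionally taken to
#' indicate adequate instrument strength.
#'
#' @param r2 Variance explained by the score.
#' @param n Sample size used to estimate it.
#' @return The F statistic; `Inf` (with a warning) when `r2 = 1`.
#' @export
f_statistic <- function(r2, n) {
  stopifnot(r2 >= 0, r2 <= 1, n > 2)
  if (r2 == 1) {
    warning("r2 = 1: F statistic is infinite")
    return(Inf)
  }
  r2 * (n - 2) / (1 - r2)
}

#' Analytic power for a binary-outcome MR analysis
#'
#' Normal-approximation power of the two-sided Wald test for a causal odds
#' ratio `or_alt` per standard deviation of the exposure, with a single
#' allele-score instrument explaining `r2` of the exposure variance in a
#' cohort of `n` individuals with case fraction `K`:
#' `power = Phi(lambda - z) + Phi(-lambda - z)` with
#' `lambda = |log(or_alt)| * sqrt(n * r2 * K * (1 - K))` and
#' `z = z_{1 - alpha/2}`. The two-term form makes power equal `alpha`
#' exactly at the null; the second term is negligible away from it.
#'
#' @param r2 Variance explained by the score, in (0,1).
#' @param n Total sample size.
#' @param case_fraction Proportion of cases, in (0,1).
#' @param or_alt Alternative-hypothesis odds ratio per SD of exposure.
#' @param alpha Two-sided test size.
#' @return Power, a probability in \[alpha, 1\].
#' @export
analytic_power <- function(r2, n, case_fraction, or_alt, alpha = 0.05) {
  stopifnot(r2 > 0, r2 < 1, n > 0,
            case_fraction > 0, case_fraction < 1,
            or_alt > 0, alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  lambda <- abs(log(or_alt)) * sqrt(n * r2 * case_fraction * (1 - case_fraction))
  stats::pnorm(lambda - z) + stats::pnorm(-lambda - z)
}

#' Instrument-strength report
#'
#' Bundles variance explained, the F statistic and analytic power for a
#' score/phenotype/outcome configuration into one record.
#'
#' @param score A `genetic_score` or numeric vector.
#' @param phenotype Measured exposure vector paired with the score.
#' @param n_outcome Sample size of the outcome analysis.
#' @param case_fraction Case fraction of the outcome analysis.
#' @param or_alt Alternative odds ratio per SD of exposure (default 1.15,
#'   a 15% effect).
#' @param alpha Two-sided test size.
#' @return A `strength_report` object (list) with fields `r2`, `f_stat`,
#'   `power`, `alpha`, `n`, `case_fraction`, `n_phenotyped`.
#' @export
strength_report <- function(score, phenotype, n_outcome, case_fraction,
                            or_alt = 1.15, alpha = 0.05) {
  r2 <- variance_explained(score, phenotype)
  structure(list(
    r2 = r2,
    f_stat = f_statistic(r2, length(score_values(score))),
    power = analytic_power(r2, n_outcome, case_fraction, or_alt, alpha),
    alpha = alpha,
    n = n_outcome,
    case_fraction = case_fraction,
    or_alt = or_alt,
    n_phenotyped = length(score_values(score))
  ), class = "strength_report")
}

#' @export
print.strength_report <- function(x, ...) {
  cat("Instrument strength\n")
  cat(sprintf("  variance explained (r2) : %.4f (n phenotyped = %d)\n",
              x$r2, x$n_phenotyped))
  cat(sprintf("  F statistic             : %.1f %s\n", x$f_stat,
              if (x$f_stat > 10) "(above the F > 10 convention)" else
                "(WEAK: below the F > 10 convention)"))
  cat(sprintf("  power for OR %.2f/SD    : %.1f%% (n = %d, %.1f%% cases, alpha = %.2f)\n",
              x$or_alt, 100 * x$power, x$n, 100 * x$case_fraction, x$alpha))
  invisible(x)
}

#' @export
as.data.frame.strength_report <- function(x, ...) {
  data.frame(r2 = x$r2, f_stat = x$f_stat, power = x$power,
             alpha = x$alpha, n = x$n, case_fraction = x$case_fraction,
             or_alt = x$or_alt, n_phenotyped = x$n_phenotyped)
}
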