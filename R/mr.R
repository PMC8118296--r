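#' MR estimate objects
#'
#' Every summary-data estimator returns an `mr_estimate`: causal log odds
#' ratio per ms of exposure with Wald standard error, 95% CI, two-sided
#' p-value, variant count, heterogeneity statistics where applicable, and
#' method label.
#'
#' @param method Method label.
#' @param beta,se Estimate (log-OR per ms) and standard error.
#' @param n_variants Number of variants used.
#' @param Q,Q_df Cochran's Q and its degrees of freedom (or `NA`).
#' @param scale Scale label, `"per-ms"` by default.
#' @param notes Free-form diagnostics list.
#' @return An `mr_estimate` object.
#' @keywords internal
new_mr_estimate <- function(method, beta, se, n_variants,
                            Q = NA_real_, Q_df = NA_real_,
                            scale = "per-ms", notes = list()) {
  beta <- unname(beta)
  se <- unname(se)
  p <- 2 * stats::pnorm(-abs(beta / se))
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                 p = p, n_variants = as.integer(n_variants),
                 Q = Q, Q_df = Q_df,
                 Q_p = if (is.na(Q)) NA_real_ else
                   stats::pchisq(Q, Q_df, lower.tail = FALSE),
                 scale = scale,
                 significance = significance_flag(p),
                 notes = notes),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d variant(s), scale %s\n",
              x$method, x$n_variants, x$scale))
  cat(sprintf("  beta %.5f (se %.5f), OR %.4f (95%% CI %.4f-%.4f), p = %.3g (%s)\n",
              x$beta, x$se, exp(x$beta), exp(x$ci_low), exp(x$ci_high),
              x$p, x$significance))
  if (!is.na(x$Q))
    cat(sprintf("  heterogeneity: Q = %.2f on %d df, p = %.3g\n",
                x$Q, x$Q_df, x$Q_p))
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) object$beta

#' @export
confint.mr_estimate <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(object$beta - z * object$se, object$beta + z * object$se)
}

#' @export
scale_per_5ms.mr_estimate <- function(result) {
  if (!identical(result$scale, "per-ms"))
    stop("estimate is on scale '", result$scale, "', not 'per-ms'")
  new_mr_estimate(result$method, result$beta * 5, result$se * 5,
                  result$n_variants, result$Q, result$Q_df,
                  scale = "per-5ms", notes = result$notes)
}

check_pairs <- function(pairs, min_n = 2L, method = "this estimator") {
  stopifnot(is.data.frame(pairs),
            all(c("beta_exposure", "se_exposure",
                  "beta_outcome", "se_outcome") %in% names(pairs)))
  if (nrow(pairs) < min_n)
    stop(method, " requires at least ", min_n, " variant(s), got ",
         nrow(pairs))
  invisible(pairs)
}

#' Single-variant Wald ratio
#'
#' The ratio estimate `beta_outcome / beta_exposure` with the first-order
#' standard error `se_outcome / |beta_exposure|` (exposure-side sampling
#' error ignored, the standard summarised-data convention).
#'
#' @param pair One-row `summary_pairs` data frame (or a row subset).
#' @return An `mr_estimate`.
#' @export
mr_wald_ratio <- function(pair) {
  check_pairs(pair, 1L, "wald_ratio")
  pair <- pair[1, ]
  if (pair$beta_exposure == 0)
    stop("wald ratio undefined: exposure beta is zero")
  new_mr_estimate("wald_ratio",
                  pair$beta_outcome / pair$beta_exposure,
                  pair$se_outcome / abs(pair$beta_exposure),
                  1L)
}

#' Inverse-variance weighted estimator
#'
#' The workhorse summary-data estimator: weighted least squares of the
#' per-variant outcome effects on the exposure effects through the origin,
#' with weights `1/se_outcome^2`. Algebraically
#' `beta = sum(w bX bY) / sum(w bX^2)`, fixed-effects
#' `se = 1/sqrt(sum(w bX^2))`; the random-effects variant inflates the SE
#' by `sqrt(max(1, Q/(J-1)))` where Q is Cochran's heterogeneity statistic
#' of the per-variant ratio estimates about the pooled slope.
#'
#' @param pairs A `summary_pairs` data frame (>= 2 variants).
#' @param effects `"fixed"` or `"random"`.
#' @return An `mr_estimate` with heterogeneity statistics.
#' @export
mr_ivw <- function(pairs, effects = c("fixed", "random")) {
  effects <- match.arg(effects)
  check_pairs(pairs, 2L, "IVW")
  w <- 1 / pairs$se_outcome^2
  bx <- pairs$beta_exposure
  by <- pairs$beta_outcome
  denom <- sum(w * bx^2)
  beta <- sum(w * bx * by) / denom
  se_fixed <- 1 / sqrt(denom)
  J <- nrow(pairs)
  Q <- sum(w * (by - beta * bx)^2)
  Q_df <- J - 1L
  se <- if (effects == "random")
    se_fixed * sqrt(max(1, Q / Q_df)) else se_fixed
  new_mr_estimate(paste0("ivw_", effects), beta, se, J, Q, Q_df,
                  notes = list(se_fixed = se_fixed))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with
#' a free intercept (weights `1/se_outcome^2`), requiring all exposure
#' betas oriented non-negative (the harmonisation contract). The slope is
#' the pleiotropy-adjusted causal estimate; the intercept estimates the
#' average directional pleiotropic effect, and its test is the standard
#' directional-pleiotropy diagnostic.
#'
#' @param pairs A `summary_pairs` data frame (>= 3 variants).
#' @return An object of class `mr_egger`: list with elements `slope` and
#'   `intercept`, both `mr_estimate`s sharing heterogeneity statistics.
#' @export
mr_egger <- function(pairs) {
  check_pairs(pairs, 3L, "MR-Egger")
  if (any(pairs$beta_exposure < 0))
    stop("MR-Egger requires pairs oriented so all exposure betas are >= 0 ",
         "(run harmonise() first)")
  bx <- pairs$beta_exposure
  by <- pairs$beta_outcome
  if (stats::var(bx) == 0)
    stop("no spread in exposure betas: Egger slope unidentified")
  w <- 1 / pairs$se_outcome^2
  # weighted normal equations for (intercept, slope)
  sw <- sum(w); swx <- sum(w * bx); swxx <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  b0 <- (swxx * swy - swx * swxy) / det
  b1 <- (sw * swxy - swx * swy) / det
  J <- nrow(pairs)
  resid <- by - b0 - b1 * bx
  Q <- sum(w * resid^2)
  Q_df <- J - 2L
  # multiplicative overdispersion, floored at 1 (standard Egger practice)
  phi <- max(1, Q / Q_df)
  se_b0 <- sqrt(phi * swxx / det)
  se_b1 <- sqrt(phi * sw / det)
  structure(list(
    slope = new_mr_estimate("egger_slope", b1, se_b1, J, Q, Q_df),
    intercept = new_mr_estimate("egger_intercept", b0, se_b0, J, Q, Q_df)
  ), class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope)
  print(x$intercept)
  invisible(x)
}

# Weighted quantile of ratio estimates at cumulative weight prob, by
# linear interpolation of the weighted empirical distribution (weights
# centred on each order statistic).
weighted_quantile <- function(ratio, weights, prob = 0.5) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (prob <= s[1]) return(r[1])
  k <- length(r)
  if (prob >= s[k]) return(r[k])
  stats::approx(s, r, xout = prob, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' The median of the per-variant ratio estimates under the weighted
#' empirical distribution with weights `bX^2 / seY^2`; consistent when at
#' least 50% of the weight comes from valid instruments. The standard
#' error is obtained by parametric bootstrap: exposure and outcome betas
#' are redrawn from normal distributions centred on their estimates.
#'
#' @param pairs A `summary_pairs` data frame (>= 2 variants).
#' @param n_boot Bootstrap draws (warns below 100).
#' @param seed Integer seed for the bootstrap (mandatory determinism).
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000L, seed = 1L) {
  check_pairs(pairs, 2L, "weighted median")
  if (n_boot < 100L) warning("n_boot < 100: bootstrap SE will be unstable")
  est <- weighted_quantile(pairs$beta_outcome / pairs$beta_exposure,
                           pairs$beta_exposure^2 / pairs$se_outcome^2)
  boots <- boot_ratio_estimates(pairs, n_boot, seed, function(bx, by, seY)
    weighted_quantile(by / bx, bx^2 / seY^2))
  new_mr_estimate("weighted_median", est, stats::sd(boots), nrow(pairs),
                  notes = list(n_boot = n_boot, seed = seed))
}

boot_ratio_estimates <- function(pairs, n_boot, seed, statistic) {
  set.seed(seed)
  J <- nrow(pairs)
  vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(J, pairs$beta_exposure, pairs$se_exposure)
    by <- stats::rnorm(J, pairs$beta_outcome, pairs$se_outcome)
    statistic(bx, by, pairs$se_outcome)
  }, numeric(1))
}

# Modified Silverman bandwidth on the ratio estimates (mode-estimator
# convention: 0.9 * min(sd, mad) * n^(-1/5)).
mode_bandwidth <- function(ratio, bandwidth_factor) {
  s <- min(stats::sd(ratio), stats::mad(ratio))
  if (s == 0) s <- abs(ratio[1]) * 1e-6 + 1e-12
  h <- bandwidth_factor * 0.9 * s * length(ratio)^(-1 / 5)
  if (h <= 0) stop("zero bandwidth: ratio estimates are degenerate")
  h
}

weighted_mode_point <- function(ratio, weights, h, n_grid = 512L) {
  w <- weights / sum(weights)
  lo <- min(ratio) - 3 * h
  hi <- max(ratio) + 3 * h
  grid <- seq(lo, hi, length.out = n_grid)
  dens <- vapply(grid, function(g)
    sum(w * stats::dnorm((g - ratio) / h)), numeric(1))
  grid[which.max(dens)]
}

#' Weighted mode estimator
#'
#' The mode of the kernel-smoothed weighted density of per-variant ratio
#' estimates (Gaussian kernel, modified-Silverman bandwidth scaled by
#' `bandwidth_factor`); consistent when the largest homogeneous cluster of
#' variants is valid, even if that cluster is a minority. SE by parametric
#' bootstrap. A bandwidth sensitivity sweep over factors {0.5, 1, 2} is
#' recorded in `notes$bandwidth_sweep`.
#'
#' @param pairs A `summary_pairs` data frame (>= 2 variants).
#' @param bandwidth_factor Multiplier on the modified-Silverman bandwidth.
#' @param n_boot Bootstrap draws.
#' @param seed Integer seed.
#' @return An `mr_estimate`.
#' @export
mr_weighted_mode <- function(pairs, bandwidth_factor = 1, n_boot = 1000L,
                             seed = 1L) {
  check_pairs(pairs, 2L, "weighted mode")
  if (bandwidth_factor <= 0) stop("zero bandwidth")
  ratio <- pairs$beta_outcome / pairs$beta_exposure
  wts <- pairs$beta_exposure^2 / pairs$se_outcome^2
  h <- mode_bandwidth(ratio, bandwidth_factor)
  est <- weighted_mode_point(ratio, wts, h)
  boots <- boot_ratio_estimates(pairs, n_boot, seed, function(bx, by, seY) {
    r <- by / bx
    weighted_mode_point(r, bx^2 / seY^2, mode_bandwidth(r, bandwidth_factor))
  })
  sweep_ <- vapply(c(0.5, 1, 2), function(f)
    weighted_mode_point(ratio, wts, mode_bandwidth(ratio, f)), numeric(1))
  names(sweep_) <- c("bw_x0.5", "bw_x1", "bw_x2")
  new_mr_estimate("weighted_mode", est, stats::sd(boots), nrow(pairs),
                  notes = list(bandwidth = h, n_boot = n_boot, seed = seed,
                               bandwidth_sweep = sweep_))
}

#' Fixed-effects meta-analysis of MR estimates
#'
#' Inverse-variance pooling of estimates on a common scale (for example
#' the biobank score estimate and an external-consortium IVW estimate),
#' with Cochran's Q across inputs.
#'
#' @param estimates List of `mr_estimate` and/or `assoc_result` objects,
#'   all on the same scale.
#' @return An `mr_estimate` labelled `meta_fixed`.
#' @export
mr_meta_fixed <- function(estimates) {
  stopifnot(is.list(estimates), length(estimates) >= 2L)
  scales <- vapply(estimates, function(e) e$scale, character(1))
  if (length(unique(scales)) != 1L)
    stop("estimates are on mixed scales: ",
         paste(unique(scales), collapse = ", "))
  b <- vapply(estimates, function(e) e$beta, numeric(1))
  s <- vapply(estimates, function(e) e$se, numeric(1))
  w <- 1 / s^2
  beta <- sum(w * b) / sum(w)
  se <- 1 / sqrt(sum(w))
  Q <- sum(w * (b - beta)^2)
  nv <- sum(vapply(estimates, function(e)
    if (!is.null(e$n_variants)) e$n_variants else NA_integer_, integer(1)),
    na.rm = TRUE)
  new_mr_estimate("meta_fixed", beta, se, max(nv, length(estimates)),
                  Q, length(estimates) - 1L, scale = scales[1])
}

#' Bidirectional MR: outcome-liability score against the exposure
#'
#' Applies the estimator suite with the roles swapped: a genetic score for
#' the outcome (e.g. AF liability) is used as the exposure and the ECG
#' interval as the outcome, to ask whether being at higher outcome risk
#' shifts the interval. When the forward estimate is supplied, the
#' dimensionless *loop gain* `|beta_reverse x beta_forward|` is reported:
#' the reverse slope is in ms per log-odds and the forward slope in
#' log-odds per ms, so their product is the fraction of the forward
#' effect that reverse causation could explain (a value near zero rules
#' out a meaningful feedback loop).
#'
#' @param reverse_pairs `summary_pairs` harmonised with the outcome
#'   liability as exposure and the ECG interval as outcome.
#' @param forward Optional forward-direction `mr_estimate`.
#' @param effects Passed to [mr_ivw()].
#' @return An `mr_estimate` labelled `bidirectional_ivw_*`, with
#'   `notes$loop_gain` when `forward` is given.
#' @export
mr_bidirectional <- function(reverse_pairs, forward = NULL,
                             effects = "fixed") {
  est <- mr_ivw(reverse_pairs, effects = effects)
  est$method <- paste0("bidirectional_", est$method)
  if (!is.null(forward))
    est$notes$loop_gain <- abs(est$beta * forward$beta)
  est
}

#' Funnel-plot data
#'
#' Per-variant ratio estimates against their precision
#' (`|beta_exposure| / se_outcome`), the table behind a summary-data MR
#' funnel plot for visualising asymmetry (directional pleiotropy).
#'
#' @param pairs A `summary_pairs` data frame.
#' @return Data frame: `id`, `ratio`, `precision`.
#' @export
funnel_data <- function(pairs) {
  check_pairs(pairs, 1L, "funnel data")
  data.frame(id = if ("id" %in% names(pairs)) pairs$id
             else seq_len(nrow(pairs)),
             ratio = pairs$beta_outcome / pairs$beta_exposure,
             precision = abs(pairs$beta_exposure) / pairs$se_outcome)
}

#' Fit a summary-data MR model
#'
#' Umbrella fitting function over the estimator suite; dispatches on
#' `method` and returns the estimator's object.
#'
#' @param pairs A harmonised `summary_pairs` data frame.
#' @param method Estimator name.
#' @param ... Passed to the underlying estimator.
#' @return An `mr_estimate` (or `mr_egger` / `presso_report` for those
#'   methods).
#' @export
mr_fit <- function(pairs,
                   method = c("ivw_fixed", "ivw_random", "egger",
                              "weighted_median", "weighted_mode",
                              "wald_ratio", "presso"),
                   ...) {
  method <- match.arg(method)
  switch(method,
         ivw_fixed = mr_ivw(pairs, "fixed"),
         ivw_random = mr_ivw(pairs, "random"),
         egger = mr_egger(pairs),
         weighted_median = mr_weighted_median(pairs, ...),
         weighted_mode = mr_weighted_mode(pairs, ...),
         wald_ratio = mr_wald_ratio(pairs),
         presso = mr_presso(pairs, ...))
}

#' Full sensitivity-analysis table
#'
#' Runs the whole estimator roster (IVW fixed and random, weighted median,
#' weighted mode, MR-Egger slope and intercept, MR-PRESSO-corrected) on one
#' harmonised pair set and assembles the comparison table reported
#' alongside a primary analysis.
#'
#' @param pairs A harmonised `summary_pairs` data frame.
#' @param n_boot Bootstrap draws for median/mode.
#' @param n_sim MR-PRESSO simulation draws.
#' @param seed Integer seed shared by the stochastic methods.
#' @param per_5ms If `TRUE`, report on the per-5-ms scale.
#' @return Data frame, one row per method: `method`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `p`, `n_variants`, `significance`.
#' @export
mr_sensitivity <- function(pairs, n_boot = 1000L, n_sim = 1000L, seed = 1L,
                           per_5ms = FALSE) {
  ests <- list(
    mr_ivw(pairs, "fixed"),
    mr_ivw(pairs, "random"),
    mr_weighted_median(pairs, n_boot, seed),
    mr_weighted_mode(pairs, 1, n_boot, seed)
  )
  if (nrow(pairs) >= 3L) {
    eg <- mr_egger(pairs)
    ests <- c(ests, list(eg$slope, eg$intercept))
  }
  if (nrow(pairs) >= 4L) {
    pr <- mr_presso(pairs, n_sim = n_sim, seed = seed)
    ests <- c(ests, list(pr$corrected))
  }
  if (per_5ms)
    ests <- lapply(ests, function(e)
      if (e$method == "egger_intercept") e else scale_per_5ms(e))
  do.call(rbind, lapply(ests, function(e)
    data.frame(method = e$method, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, p = e$p,
               n_variants = e$n_variants, significance = e$significance,
               stringsAsFactors = FALSE)))
}
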