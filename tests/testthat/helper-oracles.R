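# Independent oracles and small fixtures shared across tests.

# Independently coded IRLS for logistic regression (never calls glm).
oracle_irls_logistic <- function(X, y, max_iter = 50, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  se <- sqrt(diag(solve(crossprod(X, drop(1 / (1 + exp(-X %*% beta))) *
                                    (1 - drop(1 / (1 + exp(-X %*% beta)))) * X))))
  list(beta = unname(drop(beta)), se = unname(se))
}

# Closed-form weighted least squares of y on x with free intercept.
oracle_wls <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x^2)
  swy <- sum(w * y); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  c(intercept = (swxx * swy - swx * swxy) / det,
    slope = (sw * swxy - swx * swy) / det)
}

# Exhaustive cumulative-weight walk for the weighted median (independent of
# the approx()-based implementation).
oracle_weighted_median <- function(ratio, weights) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  k <- length(r)
  if (0.5 >= s[k]) return(r[k])
  i <- max(which(s < 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}

# Allelic (= dosage) correlation implied by the Gaussian-copula haplotype
# construction: two alleles are thresholded bivariate normals with latent
# correlation rho, so corr = (P11 - f1 f2) / sqrt(f1(1-f1) f2(1-f2)).
oracle_copula_dosage_cor <- function(f1, f2, rho) {
  a <- qnorm(f1); b <- qnorm(f2)
  p11 <- if (requireNamespace("mvtnorm", quietly = TRUE)) {
    mvtnorm::pmvnorm(upper = c(a, b),
                     corr = matrix(c(1, rho, rho, 1), 2))[1]
  } else {
    integrate(function(z) pnorm((b - rho * z) / sqrt(1 - rho^2)) * dnorm(z),
              -Inf, a)$value
  }
  (p11 - f1 * f2) / sqrt(f1 * (1 - f1) * f2 * (1 - f2))
}

# Hand-rolled summary pair set for arithmetic checks.
toy_pairs <- function() {
  data.frame(
    id = c("v1", "v2", "v3"),
    beta_exposure = c(1.0, 2.0, 0.5),
    se_exposure = c(0.1, 0.1, 0.1),
    beta_outcome = c(0.05, 0.11, 0.02),
    se_outcome = c(0.02, 0.03, 0.01)
  )
}

# Summary-level two-sample generator: draws per-variant estimates from
# their exact sampling distribution around configured truths. Used for
# estimator power/calibration checks where individual-level data adds
# nothing but runtime.
sim_summary_pairs <- function(J, causal, bx_true = NULL,
                              se_x = 0.05, se_y = 0.027,
                              pleiotropy = rep(0, J)) {
  if (is.null(bx_true)) bx_true <- runif(J, 0.3, 2)
  se_x <- rep_len(se_x, J)
  se_y <- rep_len(se_y, J)
  data.frame(
    id = paste0("v", seq_len(J)),
    beta_exposure = rnorm(J, bx_true, se_x),
    se_exposure = se_x,
    beta_outcome = rnorm(J, causal * bx_true + pleiotropy, se_y),
    se_outcome = se_y
  )
}

# Small cohort used by several files (kept cheap).
small_cohort <- function(n = 6000, m = 20, seed = 11, ...) {
  simulate_cohort(sim_config(
    n_individuals = n,
    variants = simulate_variant_table(m, seed = seed + 1),
    seed = seed, ...))
}
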