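test_that("wald ratio arithmetic and guards", {
  pair <- data.frame(beta_exposure = 2, se_exposure = 0.1,
                     beta_outcome = 1, se_outcome = 0.2)
  est <- mr_wald_ratio(pair)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
  pair$beta_outcome <- 0
  expect_equal(mr_wald_ratio(pair)$beta, 0)
  pair$beta_exposure <- 0
  expect_error(mr_wald_ratio(pair), "zero")
})

test_that("IVW equals the weighted-through-origin normal equations", {
  # printed toy pairs vs independent normal-equations solve
  tp <- toy_pairs()
  w <- 1 / tp$se_outcome^2
  beta_orc <- sum(w * tp$beta_exposure * tp$beta_outcome) /
    sum(w * tp$beta_exposure^2)
  est <- mr_ivw(tp, "fixed")
  expect_equal(est$beta, beta_orc, tolerance = 1e-12)
  expect_equal(est$se, 1 / sqrt(sum(w * tp$beta_exposure^2)),
               tolerance = 1e-12)
  # and against lm() weighted through the origin
  fit <- lm(beta_outcome ~ 0 + beta_exposure, data = tp, weights = w)
  expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-12)

  # 100 random instances, 3-50 variants
  set.seed(401)
  for (r in 1:100) {
    J <- sample(3:50, 1)
    pr <- sim_summary_pairs(J, causal = rnorm(1, 0, 0.05))
    w <- 1 / pr$se_outcome^2
    orc <- sum(w * pr$beta_exposure * pr$beta_outcome) /
      sum(w * pr$beta_exposure^2)
    expect_equal(mr_ivw(pr)$beta, orc, tolerance = 1e-10)
  }
})

test_that("a single pair duplicated J times collapses IVW to the Wald ratio", {
  pair <- data.frame(beta_exposure = 1.4, se_exposure = 0.2,
                     beta_outcome = -0.03, se_outcome = 0.015)
  pairs <- pair[rep(1, 7), ]
  expect_equal(mr_ivw(pairs)$beta, mr_wald_ratio(pair)$beta,
               tolerance = 1e-12)
  expect_error(mr_ivw(pair), "at least 2")
})

test_that("random-effects IVW never reports a smaller SE than fixed", {
  set.seed(402)
  for (r in 1:20) {
    J <- sample(3:30, 1)
    pr <- sim_summary_pairs(J, causal = 0.02,
                            pleiotropy = rnorm(J, 0, 0.05))
    f <- mr_ivw(pr, "fixed")
    re <- mr_ivw(pr, "random")
    expect_gte(re$se, f$se)
    expect_equal(re$beta, f$beta)
  }
})

test_that("Egger recovers an exact line and reduces to IVW at zero intercept", {
  # points exactly on a line: slope and intercept recovered exactly
  bx <- c(0.5, 1, 1.5, 2.2, 3)
  pr <- data.frame(beta_exposure = bx, se_exposure = 0.1,
                   beta_outcome = 0.02 + 0.4 * bx,
                   se_outcome = c(0.01, 0.02, 0.01, 0.03, 0.02))
  eg <- mr_egger(pr)
  expect_equal(eg$slope$beta, 0.4, tolerance = 1e-10)
  expect_equal(eg$intercept$beta, 0.02, tolerance = 1e-10)

  # against the closed-form WLS oracle on noisy data
  set.seed(403)
  pr2 <- sim_summary_pairs(20, causal = -0.01, pleiotropy = rep(0.02, 20))
  eg2 <- mr_egger(pr2)
  orc <- oracle_wls(pr2$beta_exposure, pr2$beta_outcome,
                    1 / pr2$se_outcome^2)
  expect_equal(eg2$slope$beta, unname(orc["slope"]), tolerance = 1e-10)
  expect_equal(eg2$intercept$beta, unname(orc["intercept"]),
               tolerance = 1e-10)

  # forcing the intercept to zero reproduces fixed-effects IVW exactly:
  # the through-origin weighted normal equation IS the IVW formula
  w <- 1 / pr2$se_outcome^2
  b_zero_int <- sum(w * pr2$beta_exposure * pr2$beta_outcome) /
    sum(w * pr2$beta_exposure^2)
  expect_equal(b_zero_int, mr_ivw(pr2)$beta, tolerance = 1e-14)

  expect_error(mr_egger(pr2[1:2, ]), "at least 3")
  pr3 <- pr2; pr3$beta_exposure <- 1
  expect_error(mr_egger(pr3), "spread")
  pr4 <- pr2; pr4$beta_exposure[1] <- -0.5
  expect_error(mr_egger(pr4), "oriented|>= 0")
})

test_that("weighted median matches the exhaustive cumulative-weight walk", {
  # all ratios equal: estimate equals that constant for any weights
  pr <- data.frame(beta_exposure = c(1, 2, 4), se_exposure = 0.1,
                   beta_outcome = c(0.3, 0.6, 1.2),
                   se_outcome = c(0.01, 0.05, 0.02))
  expect_equal(mr_weighted_median(pr, 100, 1)$beta, 0.3, tolerance = 1e-12)

  # hand-computable 5-pair instance plus random <= 10-variant instances
  set.seed(404)
  for (r in 1:25) {
    J <- sample(2:10, 1)
    prr <- sim_summary_pairs(J, causal = 0.05)
    ratio <- prr$beta_outcome / prr$beta_exposure
    wts <- prr$beta_exposure^2 / prr$se_outcome^2
    est <- mr_weighted_median(prr, 100, seed = r)
    expect_equal(est$beta, oracle_weighted_median(ratio, wts),
                 tolerance = 1e-12)
    expect_gte(est$beta, min(ratio))
    expect_lte(est$beta, max(ratio))
  }
  expect_warning(mr_weighted_median(pr, 50, 1), "n_boot")
})

test_that("weighted median resists 40% invalid instruments; IVW does not", {
  # With 40% of variants carrying large one-sided direct effects, the
  # weighted median sits at an upper quantile of the *valid* ratio
  # distribution, so its residual bias is bounded by the per-variant
  # ratio noise (it vanishes as instrument SEs shrink), while the IVW
  # estimate absorbs the full pleiotropic mean shift.
  set.seed(405)
  J <- 20
  n_bad <- 8
  truth <- 0.02
  reps <- 60
  med <- ivw <- numeric(reps)
  bx <- runif(J, 0.5, 2)
  se_y <- 0.01
  for (r in seq_len(reps)) {
    plei <- c(rep(0.15, n_bad), rep(0, J - n_bad))  # large direct effects
    pr <- sim_summary_pairs(J, causal = truth, bx_true = bx,
                            se_y = se_y, pleiotropy = plei)
    med[r] <- mr_weighted_median(pr, 100, seed = r)$beta
    ivw[r] <- mr_ivw(pr)$beta
  }
  bias_med <- mean(med) - truth
  bias_ivw <- mean(ivw) - truth
  ratio_noise <- mean(se_y / bx)  # per-variant ratio SD scale
  expect_lt(abs(bias_med), 2 * ratio_noise)
  expect_gt(bias_ivw, 3 * abs(bias_med))  # IVW absorbs the direct effects
  expect_gt(bias_ivw, truth)               # materially biased upward
})

test_that("weighted mode finds the dominant cluster", {
  # tight cluster: mode at the cluster centre
  pr <- data.frame(beta_exposure = rep(1, 6), se_exposure = 0.05,
                   beta_outcome = 0.1 + c(-1, 1, -2, 2, 0, 0) * 1e-4,
                   se_outcome = 0.02)
  est <- mr_weighted_mode(pr, 1, 100, 1)
  expect_lt(abs(est$beta - 0.1), 1e-3)

  # bimodal: 60% of weight at 0.1, 40% at 0.5 -> returns ~ 0.1
  set.seed(406)
  pr2 <- data.frame(
    beta_exposure = rep(1, 10), se_exposure = 0.05,
    beta_outcome = c(rnorm(6, 0.1, 0.005), rnorm(4, 0.5, 0.005)),
    se_outcome = 0.02)
  est2 <- mr_weighted_mode(pr2, 1, 100, 2)
  expect_lt(abs(est2$beta - 0.1), 0.05)
  ratio <- pr2$beta_outcome / pr2$beta_exposure
  expect_gte(est2$beta, min(ratio))
  expect_lte(est2$beta, max(ratio))

  # oracle: fine-grid evaluation of the weighted kernel density
  wts <- pr2$beta_exposure^2 / pr2$se_outcome^2
  h <- est2$notes$bandwidth
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 20001)
  dens <- sapply(grid, function(g)
    sum(wts / sum(wts) * dnorm((g - ratio) / h)))
  expect_lt(abs(est2$beta - grid[which.max(dens)]), 1e-3)

  # bandwidth sweep surfaced in the notes
  expect_named(est2$notes$bandwidth_sweep, c("bw_x0.5", "bw_x1", "bw_x2"))
  expect_error(mr_weighted_mode(pr2, 0), "bandwidth")
})

test_that("stochastic estimators are bit-reproducible under fixed seeds", {
  set.seed(407)
  pr <- sim_summary_pairs(15, causal = 0.03)
  a <- mr_weighted_median(pr, 300, seed = 99)
  b <- mr_weighted_median(pr, 300, seed = 99)
  expect_identical(a$beta, b$beta)
  expect_identical(a$se, b$se)
  c_ <- mr_weighted_median(pr, 300, seed = 100)
  expect_false(identical(a$se, c_$se))
  m1 <- mr_weighted_mode(pr, 1, 200, seed = 7)
  m2 <- mr_weighted_mode(pr, 1, 200, seed = 7)
  expect_identical(m1$se, m2$se)
  p1 <- mr_presso(pr, n_sim = 300, seed = 5)
  p2 <- mr_presso(pr, n_sim = 300, seed = 5)
  expect_identical(p1$global_p, p2$global_p)
  expect_identical(p1$outliers$p, p2$outliers$p)
})

test_that("fixed-effects meta-analysis pools by inverse variance", {
  e1 <- ecgmr:::new_mr_estimate("ivw_fixed", -0.06, 0.01, 10)
  e2 <- ecgmr:::new_mr_estimate("ivw_fixed", -0.05, 0.02, 12)
  m <- mr_meta_fixed(list(e1, e2))
  w <- c(1 / 0.01^2, 1 / 0.02^2)
  expect_equal(m$beta, sum(w * c(-0.06, -0.05)) / sum(w), tolerance = 1e-12)
  expect_equal(m$beta, -0.058, tolerance = 1e-10)
  expect_equal(m$se, 0.00894, tolerance = 1e-3)

  # two identical estimates: pooled (b, s/sqrt(2))
  m2 <- mr_meta_fixed(list(e1, e1))
  expect_equal(m2$beta, -0.06)
  expect_equal(m2$se, 0.01 / sqrt(2), tolerance = 1e-12)

  # convexity: pooled estimate lies between the inputs
  set.seed(408)
  for (r in 1:20) {
    b <- rnorm(2); s <- runif(2, 0.01, 0.1)
    ee <- list(ecgmr:::new_mr_estimate("a", b[1], s[1], 2),
               ecgmr:::new_mr_estimate("b", b[2], s[2], 2))
    mm <- mr_meta_fixed(ee)
    expect_gte(mm$beta, min(b) - 1e-12)
    expect_lte(mm$beta, max(b) + 1e-12)
  }

  # mixed scales refuse to pool
  e3 <- scale_per_5ms(e2)
  expect_error(mr_meta_fixed(list(e1, e3)), "mixed scales")
})

test_that("bidirectional analysis separates causal directions", {
  # forward-only world: reverse estimate ~ 0
  v <- simulate_variant_table(15, seed = 411)
  co <- simulate_cohort(sim_config(n_individuals = 40000, variants = v,
                                   seed = 412))
  fwd <- mr_ivw(make_summary_pairs(co))
  # reverse world: variants act on outcome liability only; the interval
  # responds to liability with 0 ms per log-odds (no reverse path)
  v_rev <- v; v_rev$beta <- 0
  co_rev <- simulate_cohort(sim_config(
    n_individuals = 40000, variants = v_rev, target_r2 = NULL,
    causal_beta = 0, pleiotropy = 0.2 * sign(v$beta), seed = 413))
  rp <- make_reverse_pairs(co_rev)
  bid <- mr_bidirectional(rp, forward = fwd)
  expect_lt(abs(bid$beta), 3 * bid$se)  # null reverse direction
  expect_true(is.finite(bid$notes$loop_gain))

  # reverse path configured: liability shifts the interval
  v_rev2 <- v
  v_rev2$beta <- 0.2 * sign(v$beta) * 5  # 5 ms per unit liability effect
  co_rev2 <- simulate_cohort(sim_config(
    n_individuals = 40000, variants = v_rev2, target_r2 = NULL,
    causal_beta = 0, pleiotropy = 0.2 * sign(v$beta), seed = 414))
  rp2 <- make_reverse_pairs(co_rev2)
  bid2 <- mr_bidirectional(rp2)
  expect_gt(bid2$beta, 3 * bid2$se)  # recovered positive reverse effect
})

test_that("mr_fit dispatches across the estimator suite", {
  set.seed(421)
  pr <- sim_summary_pairs(10, causal = 0.02)
  expect_identical(mr_fit(pr, "ivw_fixed")$beta, mr_ivw(pr)$beta)
  expect_s3_class(mr_fit(pr, "egger"), "mr_egger")
  expect_s3_class(mr_fit(pr, "presso", n_sim = 200, seed = 1),
                  "presso_report")
  sens <- mr_sensitivity(pr, n_boot = 100, n_sim = 200, seed = 1,
                         per_5ms = TRUE)
  expect_setequal(sens$method,
                  c("ivw_fixed", "ivw_random", "weighted_median",
                    "weighted_mode", "egger_slope", "egger_intercept",
                    "presso_corrected"))
  fd <- funnel_data(pr)
  expect_equal(fd$ratio, pr$beta_outcome / pr$beta_exposure)
})
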