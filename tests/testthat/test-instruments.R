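test_that("significance filter is strict at the threshold", {
  v <- data.frame(id = c("a", "b", "c"), chr = "1", pos = 1:3,
                  p = c(1e-9, 5e-8, 1e-7))
  out <- gw_significance_filter(v, 5e-8)
  expect_identical(out$id, "a")
  # order preserved
  v2 <- data.frame(id = c("z", "y", "x"), p = c(1e-10, 0.5, 1e-12))
  expect_identical(gw_significance_filter(v2)$id, c("z", "x"))
  expect_warning(gw_significance_filter(data.frame(id = "a", p = 0.5)),
                 "no variant")
})

test_that("filter retains true-effect variants found by per-variant regression", {
  co <- small_cohort(n = 40000, m = 15, seed = 61)
  pr <- make_summary_pairs(co, 0.5)
  v <- co$variants[match(pr$id, co$variants$id), ]
  # variants whose expected per-variant z on the exposure side is >> the
  # genome-wide threshold (z ~ 5.45): retained with high probability
  exp_z <- abs(v$beta) * sqrt(20000 * 2 * v$eaf * (1 - v$eaf)) /
    sd(co$exposure)
  truly_strong <- exp_z > 8
  expect_gt(sum(truly_strong), 0)
  kept <- gw_significance_filter(
    data.frame(id = pr$id, p = pr$p_exposure), 5e-8)$id
  expect_true(all(pr$id[truly_strong] %in% kept))
})

test_that("clumping keeps the smaller p of a correlated in-window pair", {
  v <- data.frame(id = c("a", "b"), chr = c("1", "1"),
                  pos = c(1e6, 1e6 + 1e5), p = c(1e-20, 1e-10))
  ld <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(v$id, v$id))
  out <- ld_clump(v, ld)
  expect_identical(out$id, "a")
  # r2 = 0 everywhere: everything retained
  ld0 <- matrix(0, 2, 2, dimnames = list(v$id, v$id)); diag(ld0) <- 1
  expect_identical(ld_clump(v, ld0)$id, c("a", "b"))
  # outside the window: both retained even at high r2
  v$pos[2] <- v$pos[1] + 3e5
  expect_identical(ld_clump(v, ld)$id, c("a", "b"))
})

test_that("clumping matches the brute-force greedy definition on LD blocks", {
  set.seed(71)
  n_blocks <- 4
  per <- 5
  v <- data.frame(
    id = paste0("v", 1:(n_blocks * per)),
    chr = as.character(rep(1:2, each = n_blocks * per / 2)),
    pos = as.integer(rep(seq(1e6, by = 5e4, length.out = per), n_blocks) +
                       rep((0:(n_blocks - 1)) %% 2 * 1e7, each = per)),
    p = 10^runif(n_blocks * per, -30, -8))
  block <- rep(1:n_blocks, each = per)
  r2 <- outer(block, block, function(a, b) ifelse(a == b, 0.8, 0.001))
  diag(r2) <- 1
  dimnames(r2) <- list(v$id, v$id)
  out <- ld_clump(v, r2)

  # independent re-derivation of the greedy rule
  ord <- order(v$p)
  kept <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (k in kept)
      if (v$chr[k] == v$chr[i] && abs(v$pos[k] - v$pos[i]) <= 250000 &&
          r2[v$id[i], v$id[k]] >= 0.01) conflict <- TRUE
    if (!conflict) kept <- c(kept, i)
  }
  expect_setequal(out$id, v$id[kept])

  # idempotence
  out2 <- ld_clump(out, r2)
  expect_identical(out2$id, out$id)

  # retained set is pairwise independent within windows
  for (i in seq_len(nrow(out)))
    for (j in seq_len(nrow(out)))
      if (i < j && out$chr[i] == out$chr[j] &&
          abs(out$pos[i] - out$pos[j]) <= 250000)
        expect_lt(r2[out$id[i], out$id[j]], 0.01)
})

test_that("missing LD for an in-window pair is treated as dependent and logged", {
  v <- data.frame(id = c("a", "b"), chr = "1", pos = c(1e6, 1.1e6),
                  p = c(1e-20, 1e-10))
  out <- ld_clump(v, function(i, j) NA_real_)
  expect_identical(out$id, "a")
  log <- attr(out, "clump_log")
  expect_true("missing_ld_treated_dependent" %in% log$event)
})

test_that("harmonisation flips jointly, drops palindromes, resolves strands", {
  expo <- data.frame(id = c("s1", "s2", "s3", "s4", "s5"),
                     effect_allele = c("A", "A", "C", "A", "A"),
                     other_allele = c("G", "T", "T", "C", "C"),
                     eaf = c(0.3, 0.50, 0.2, 0.4, 0.25),
                     beta = c(-2, 1, 1.5, 2, 1),
                     se = rep(0.1, 5), p = rep(1e-10, 5))
  outc <- data.frame(id = c("s1", "s2", "s3", "s4", "s5"),
                     effect_allele = c("A", "A", "A", "A", "A"),
                     other_allele = c("G", "T", "G", "C", "G"),
                     beta = c(0.01, 0.02, 0.03, 0.04, 0.05),
                     se = rep(0.01, 5))
  h <- harmonise(expo, outc)
  log <- attr(h, "harmonise_log")

  # s1: exposure beta -2 for A -> re-coded to G with beta +2, outcome -0.01
  r1 <- h[h$id == "s1", ]
  expect_equal(r1$effect_allele, "G")
  expect_equal(r1$beta_exposure, 2)
  expect_equal(r1$beta_outcome, -0.01)
  expect_equal(r1$eaf, 0.7)

  # s2: palindromic A/T at eaf 0.5 -> dropped
  expect_false("s2" %in% h$id)
  expect_equal(log$reason[log$id == "s2"], "palindromic_ambiguous")

  # s3: outcome reported on the other strand, swapped alleles (G/A vs C/T)
  r3 <- h[h$id == "s3", ]
  expect_equal(r3$beta_outcome, -0.03)
  expect_equal(log$reason[log$id == "s3"], "strand_flip_swap")

  # s5: irreconcilable allele sets -> dropped with reason
  expect_false("s5" %in% h$id)
  expect_equal(log$reason[log$id == "s5"], "allele_mismatch")

  # all outputs oriented to the lengthening allele
  expect_true(all(h$beta_exposure >= 0))
})

test_that("harmonisation is involution-safe", {
  expo <- data.frame(id = paste0("v", 1:6),
                     effect_allele = c("A", "C", "G", "T", "A", "C"),
                     other_allele = c("G", "A", "C", "G", "C", "T"),
                     eaf = c(0.3, 0.6, 0.2, 0.8, 0.35, 0.7),
                     beta = c(2, -1, 3, -2, 1, -0.5),
                     se = rep(0.1, 6), p = rep(1e-9, 6))
  outc <- data.frame(id = expo$id,
                     effect_allele = expo$effect_allele,
                     other_allele = expo$other_allele,
                     beta = c(0.02, -0.01, 0.04, -0.02, 0.01, -0.01),
                     se = rep(0.01, 6))
  h1 <- harmonise(expo, outc)
  # feed the harmonised set back in as both sides: nothing may change
  expo2 <- data.frame(id = h1$id, effect_allele = h1$effect_allele,
                      other_allele = h1$other_allele, eaf = h1$eaf,
                      beta = h1$beta_exposure, se = h1$se_exposure,
                      p = h1$p_exposure)
  outc2 <- data.frame(id = h1$id, effect_allele = h1$effect_allele,
                      other_allele = h1$other_allele,
                      beta = h1$beta_outcome, se = h1$se_outcome)
  h2 <- harmonise(expo2, outc2)
  expect_equal(h2$beta_exposure, h1$beta_exposure)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$effect_allele, h1$effect_allele)
})

test_that("randomly strand-flipped records harmonise to the causal ratio", {
  co <- small_cohort(n = 40000, m = 12, seed = 81)
  pr <- make_summary_pairs(co, 0.5, orient = FALSE)
  expo <- data.frame(id = pr$id, effect_allele = pr$effect_allele,
                     other_allele = pr$other_allele, eaf = pr$eaf,
                     beta = pr$beta_exposure, se = pr$se_exposure,
                     p = pr$p_exposure)
  outc <- data.frame(id = pr$id, effect_allele = pr$effect_allele,
                     other_allele = pr$other_allele,
                     beta = pr$beta_outcome, se = pr$se_outcome)
  # strand-flip a subset of outcome records (non-palindromic stay resolvable)
  set.seed(82)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- runif(nrow(outc)) < 0.4
  outc$effect_allele[flip] <- comp[outc$effect_allele[flip]]
  outc$other_allele[flip] <- comp[outc$other_allele[flip]]
  h <- harmonise(expo, outc)
  expect_gt(nrow(h), 0)
  strong <- h$beta_exposure / h$se_exposure > 12
  ratio <- h$beta_outcome[strong] / h$beta_exposure[strong]
  ratio_se <- h$se_outcome[strong] / h$beta_exposure[strong]
  expect_true(all(abs(ratio - co$config$causal_beta) < 4 * ratio_se))
})

test_that("ion-channel subsetting retains annotation matches only", {
  v <- simulate_variant_table(20, seed = 91)
  v$gene <- rep(c("SCN5A", "TTN", "KCNQ1", "MYH6"), 5)
  out <- ion_channel_subset(v, c("SCN5A", "KCNQ1"))
  expect_equal(nrow(out), 10)
  expect_true(all(out$gene %in% c("SCN5A", "KCNQ1")))
  expect_equal(out$beta, v$beta[v$gene %in% c("SCN5A", "KCNQ1")])
  expect_warning(ion_channel_subset(v, "NOSUCHGENE"), "fewer than 2")
  suppressWarnings(
    expect_equal(nrow(ion_channel_subset(v, character(0))), 0))
})
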