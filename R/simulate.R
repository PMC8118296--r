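#' Simulation configuration for a synthetic genotyped cohort
#'
#' Describes the data-generating world for a cohort in which a weighted
#' allele score instruments an ECG interval (in milliseconds) and the
#' interval has a configurable causal effect, on the log-odds scale, on a
#' binary arrhythmia outcome. The defaults reproduce the PR-interval
#' scenario used throughout the package: 52 variants explaining 5.0% of the
#' interval variance, a population mean of 163 ms with SD 27 ms, outcome
#' prevalence 19,132/278,792, and a causal odds ratio of 0.94 per 5 ms.
#'
#' @param n_individuals Cohort size.
#' @param variants Data frame with at least columns `id`, `eaf`
#'   (effect-allele frequency, strictly inside (0,1)) and `beta` (per-allele
#'   effect on the exposure, ms). See [simulate_variant_table()].
#' @param target_r2 Fraction of exposure variance explained by the true
#'   weighted score, in (0,1), or `NULL` for a pure-score exposure with a
#'   fixed residual SD of 1 ms.
#' @param causal_beta Causal effect of the exposure on the outcome, log-odds
#'   per 1 ms.
#' @param baseline_prevalence Marginal outcome probability, in (0,1).
#' @param mean_exposure,sd_exposure Population mean and SD of the exposure
#'   (ms). When `sd_exposure` is given, the variant weights are rescaled so
#'   that the score explains `target_r2` of `sd_exposure^2`; the rescaled
#'   weights are recorded in the cohort's variant table.
#' @param confounder_exposure,confounder_outcome Effect of a latent
#'   standard-normal confounder on the exposure (ms per unit) and on the
#'   outcome (log-odds per unit). Both default to 0 (no confounding).
#' @param pleiotropy Per-variant direct effects on the outcome log-odds,
#'   bypassing the exposure; a numeric vector of length `nrow(variants)` or
#'   `NULL` for none.
#' @param ld_blocks Optional list of integer vectors partitioning (a subset
#'   of) variant indices into linkage-disequilibrium blocks.
#' @param ld_r Within-block haplotype correlation in \[0, 1); scalar or one
#'   value per block.
#' @param n_pcs Number of standard-normal covariate columns mimicking
#'   principal components of ancestry (null effects by default).
#' @param pc_outcome Optional vector of log-odds effects of the PC columns
#'   on the outcome, for population-structure confounding scenarios.
#' @param seed Integer seed; a fixed seed makes every cohort byte-identical.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_variant_table()]
#' @export
sim_config <- function(n_individuals = 10000,
                       variants = simulate_variant_table(52, seed = 1L),
                       target_r2 = 0.05,
                       causal_beta = log(0.94) / 5,
                       baseline_prevalence = 19132 / 278792,
                       mean_exposure = 163,
                       sd_exposure = 27,
                       confounder_exposure = 0,
                       confounder_outcome = 0,
                       pleiotropy = NULL,
                       ld_blocks = NULL,
                       ld_r = 0,
                       n_pcs = 4,
                       pc_outcome = NULL,
                       seed = 1L) {
  stopifnot(is.data.frame(variants),
            all(c("id", "eaf", "beta") %in% names(variants)))
  if (any(variants$eaf <= 0 | variants$eaf >= 1))
    stop("effect-allele frequencies must lie strictly inside (0, 1)")
  if (!is.null(target_r2) &&
      (!is.numeric(target_r2) || target_r2 <= 0 || target_r2 >= 1))
    stop("target_r2 must lie in (0, 1)")
  if (!is.null(target_r2) && all(variants$beta == 0))
    stop("target_r2 > 0 is impossible when every variant weight is zero")
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1)
    stop("baseline_prevalence must lie in (0, 1)")
  if (!is.null(pleiotropy) && length(pleiotropy) != nrow(variants))
    stop("pleiotropy must have one entry per variant")
  if (!is.null(ld_blocks)) {
    idx <- unlist(ld_blocks)
    if (anyDuplicated(idx) || any(idx < 1 | idx > nrow(variants)))
      stop("ld_blocks must be disjoint subsets of variant indices")
    ld_r <- rep_len(ld_r, length(ld_blocks))
    if (any(ld_r < 0 | ld_r >= 1))
      stop("within-block haplotype correlation must lie in [0, 1)")
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    variants = variants,
    target_r2 = target_r2,
    causal_beta = causal_beta,
    baseline_prevalence = baseline_prevalence,
    mean_exposure = mean_exposure,
    sd_exposure = sd_exposure,
    confounder_exposure = confounder_exposure,
    confounder_outcome = confounder_outcome,
    pleiotropy = pleiotropy,
    ld_blocks = ld_blocks,
    ld_r = ld_r,
    n_pcs = as.integer(n_pcs),
    pc_outcome = pc_outcome,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic variant-weight table
#'
#' Emulates the published per-allele weight tables used to build an ECG
#' genetic score: one row per variant with identifier, position, alleles,
#' effect-allele frequency and per-allele effect on the interval (ms) with
#' its standard error and p-value. Effects are drawn so that a realistic
#' minority of variants carry most of the weight, frequencies are uniform on
#' (0.05, 0.95), and every row is genome-wide significant by construction
#' (these tables stand in for already-selected instruments).
#'
#' @param n_variants Number of variants.
#' @param seed Integer seed.
#' @param chromosomes Chromosomes to scatter variants across.
#' @param gwas_n Nominal discovery-study size; determines the standard
#'   errors and the smallest effect compatible with selection.
#' @param pheno_sd Phenotype SD (ms) in the emulated discovery study.
#' @param effect_excess Mean of the exponential excess of the allelic
#'   effect above the selection threshold, as a multiple of the threshold
#'   (a few hits just above threshold, occasional large loci).
#' @param gene_pool Gene symbols sampled for the `gene` annotation column;
#'   the first few are ion-channel loci so channel subsetting is exercised.
#' @return A data frame with columns `id`, `chr`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `p`, `gene`.
#' @export
simulate_variant_table <- function(n_variants = 52, seed = 1L,
                                   chromosomes = 1:22,
                                   gwas_n = 90000,
                                   pheno_sd = 27,
                                   effect_excess = 0.8,
                                   gene_pool = c("SCN5A", "SCN10A", "KCNQ1",
                                                 "KCNJ2", "MYH6", "TBX5",
                                                 "CAV1", "NKX2-5", "ARHGAP24",
                                                 "TTN", "PITX2", "MEIS1")) {
  set.seed(seed)
  chr <- sort(sample(chromosomes, n_variants, replace = TRUE))
  pos <- integer(n_variants)
  for (c_ in unique(chr)) {
    k <- sum(chr == c_)
    pos[chr == c_] <- sort(sample.int(2.4e8, k))
  }
  eaf <- stats::runif(n_variants, 0.05, 0.95)
  # effects drawn from the *selected* tail: on the allelic-SD scale the
  # smallest effect is the one detectable at P < 5e-8 in the discovery
  # study, with an exponential excess above it (many hits near threshold,
  # a few large loci); per-allele ms effects then scale inversely with
  # sqrt(2f(1-f)), as selection induces in real GWAS hits
  z_gw <- stats::qnorm(1 - 2.5e-8)
  u_min <- z_gw * pheno_sd / sqrt(gwas_n)
  u <- u_min * (1 + stats::rexp(n_variants, rate = 1 / effect_excess))
  sgn <- sample(c(-1, 1), n_variants, replace = TRUE)
  beta <- sgn * u / sqrt(2 * eaf * (1 - eaf))
  se <- pheno_sd / sqrt(2 * eaf * (1 - eaf) * gwas_n)
  p <- 2 * stats::pnorm(-abs(beta) / se)
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, n_variants, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), character(1))
  data.frame(
    id = sprintf("rs%07d", sample.int(9999999, n_variants)),
    chr = as.character(chr),
    pos = pos,
    effect_allele = ea,
    other_allele = oa,
    eaf = eaf,
    beta = beta,
    se = se,
    p = p,
    gene = sample(gene_pool, n_variants, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulate genotype dosages
#'
#' Draws biallelic dosages in Hardy–Weinberg proportions. Independent
#' variants are binomial(2, f); variants inside a linkage-disequilibrium
#' block are generated from two latent Gaussian-copula haplotypes per
#' individual, which preserves the exact Hardy–Weinberg margins while
#' inducing a tunable within-block allelic correlation.
#'
#' @param config A [sim_config()].
#' @return An `n x m` integer dosage matrix with entries in `{0, 1, 2}` and
#'   variant ids as column names.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  f <- config$variants$eaf
  m <- length(f)
  geno <- matrix(0L, n, m, dimnames = list(NULL, config$variants$id))
  in_block <- logical(m)
  if (!is.null(config$ld_blocks)) {
    for (b in seq_along(config$ld_blocks)) {
      idx <- config$ld_blocks[[b]]
      in_block[idx] <- TRUE
      geno[, idx] <- ld_block_dosages(n, f[idx], config$ld_r[b])
    }
  }
  free <- which(!in_block)
  if (length(free))
    geno[, free] <- matrix(
      stats::rbinom(n * length(free), 2L, rep(f[free], each = n)),
      n, length(free)
    )
  geno
}

# Two correlated latent haplotypes per individual: each haplotype is a
# thresholded draw from an exchangeable multivariate normal with correlation
# rho, allele = 1 when the latent value falls below qnorm(f). Margins are
# exactly binomial(2, f); the allelic correlation is the tetrachoric-induced
# correlation of the copula, not rho itself.
ld_block_dosages <- function(n, f, rho) {
  k <- length(f)
  if (k == 1L || rho == 0)
    return(matrix(stats::rbinom(n * k, 2L, rep(f, each = n)), n, k))
  R <- matrix(rho, k, k); diag(R) <- 1
  L <- chol(R)
  thr <- stats::qnorm(f)
  hap <- function() {
    z <- matrix(stats::rnorm(n * k), n, k) %*% L
    sweep(z, 2, thr, "<") * 1L
  }
  h <- hap() + hap()
  storage.mode(h) <- "integer"
  h
}

#' Simulate the exposure from genotypes
#'
#' Builds the exposure (an ECG interval in ms) as the true weighted allele
#' score plus Gaussian noise: `X_i = c + sum_j w_j g_ij + e_i`. The noise
#' variance is chosen so that the score explains `target_r2` of the realised
#' exposure variance; when the configuration fixes a population SD, the
#' weights are first rescaled so the score variance equals
#' `target_r2 * sd_exposure^2`. The intercept centres the population mean on
#' `mean_exposure`.
#'
#' @param genotypes Dosage matrix from [simulate_genotypes()].
#' @param config A [sim_config()].
#' @return Numeric exposure vector (ms), with attributes `weights`
#'   (the effective per-allele weights used), `noise_sd` and `intercept`.
#' @export
simulate_exposure <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$variants$beta
  score <- drop(genotypes %*% w)
  v_score <- stats::var(score)
  if (!is.null(config$target_r2)) {
    if (v_score == 0)
      stop("target_r2 > 0 is impossible: the true score has zero variance")
    r2 <- config$target_r2
    if (!is.null(config$sd_exposure)) {
      scale <- config$sd_exposure * sqrt(r2 / v_score)
      w <- w * scale
      score <- score * scale
      v_score <- v_score * scale^2
    }
    noise_sd <- sqrt(v_score * (1 - r2) / r2)
  } else {
    # no variance-explained target: residual SD defaults to the configured
    # population SD (or 1 ms), e.g. for outcome-liability instrument worlds
    # where the variants explain none of the interval
    noise_sd <- if (!is.null(config$sd_exposure)) config$sd_exposure else 1
  }
  u <- attr(genotypes, "confounder")
  conf_term <- if (!is.null(u)) config$confounder_exposure * u else 0
  x <- score + conf_term + stats::rnorm(length(score), 0, noise_sd)
  intercept <- config$mean_exposure - mean(score)
  x <- x + intercept
  structure(x, weights = stats::setNames(w, config$variants$id),
            noise_sd = noise_sd, intercept = intercept)
}

#' Simulate a binary outcome under a logistic causal model
#'
#' `P(Y = 1) = logistic(alpha + causal_beta * (X - mean(X)) + confounder and
#' per-variant pleiotropy terms)`, with the intercept `alpha` solved
#' numerically so that the marginal prevalence equals
#' `baseline_prevalence`. Pleiotropic effects act on the log-odds scale via
#' centred dosages, bypassing the exposure.
#'
#' @param exposure Exposure vector from [simulate_exposure()].
#' @param genotypes Dosage matrix.
#' @param config A [sim_config()].
#' @param confounder Optional latent confounder vector (standard normal).
#' @return Integer 0/1 outcome vector with attribute `alpha`.
#' @export
simulate_outcome <- function(exposure, genotypes, config, confounder = NULL) {
  stopifnot(inherits(config, "sim_config"))
  eta <- config$causal_beta * (exposure - mean(exposure))
  if (!is.null(confounder))
    eta <- eta + config$confounder_outcome * confounder
  if (!is.null(config$pleiotropy)) {
    gc <- sweep(genotypes, 2, 2 * config$variants$eaf)
    eta <- eta + drop(gc %*% config$pleiotropy)
  }
  if (!is.null(config$pc_outcome) && !is.null(attr(genotypes, "pcs")))
    eta <- eta + drop(attr(genotypes, "pcs") %*% config$pc_outcome)
  K <- config$baseline_prevalence
  alpha <- stats::uniroot(
    function(a) mean(stats::plogis(a + eta)) - K,
    lower = stats::qlogis(K) - 10, upper = stats::qlogis(K) + 10,
    tol = 1e-10
  )$root
  y <- stats::rbinom(length(eta), 1L, stats::plogis(alpha + eta))
  structure(as.integer(y), alpha = alpha)
}

#' Simulate a complete cohort
#'
#' One call generating genotypes, exposure, outcome, covariates (sex and
#' genotyping-array indicators plus standard-normal principal-component-like
#' columns) and the latent confounder, reproducibly from the configuration
#' seed.
#'
#' @param config A [sim_config()].
#' @return An object of class `ecg_cohort`: a list with elements
#'   `genotypes`, `exposure`, `outcome`, `covariates` (data frame),
#'   `confounder`, `variants` (weight table with the effective weights in
#'   column `beta`), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  geno <- simulate_genotypes(config)
  u <- stats::rnorm(n)
  attr(geno, "confounder") <- u
  x <- simulate_exposure(geno, config)
  attr(geno, "confounder") <- NULL
  pcs <- NULL
  if (config$n_pcs > 0) {
    pcs <- matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs,
                  dimnames = list(NULL, paste0("PC", seq_len(config$n_pcs))))
    attr(geno, "pcs") <- pcs
  }
  y <- simulate_outcome(as.numeric(x), geno, config, confounder = u)
  attr(geno, "pcs") <- NULL
  cov <- data.frame(sex = stats::rbinom(n, 1L, 0.46),
                    array = stats::rbinom(n, 1L, 0.9))
  if (!is.null(pcs)) cov <- cbind(cov, as.data.frame(pcs))
  variants <- config$variants
  variants$beta <- as.numeric(attr(x, "weights"))
  structure(list(
    genotypes = geno,
    exposure = as.numeric(x),
    outcome = as.integer(y),
    covariates = cov,
    confounder = u,
    variants = variants,
    config = config
  ), class = "ecg_cohort")
}

#' @export
print.ecg_cohort <- function(x, ...) {
  cat("Synthetic genotyped cohort\n")
  cat(sprintf("  individuals : %d\n", length(x$exposure)))
  cat(sprintf("  variants    : %d\n", ncol(x$genotypes)))
  cat(sprintf("  exposure    : mean %.1f ms, sd %.1f ms\n",
              mean(x$exposure), stats::sd(x$exposure)))
  cat(sprintf("  outcome     : %d cases (%.2f%%)\n",
              sum(x$outcome), 100 * mean(x$outcome)))
  invisible(x)
}

#' Two-sample summary statistics from a cohort split
#'
#' Splits the cohort into two disjoint subsamples; estimates per-variant
#' exposure effects (simple linear regression of exposure on dosage) in the
#' first and per-variant outcome log-odds ratios (logistic regression of
#' outcome on dosage) in the second, so the resulting summary pairs have the
#' non-overlapping two-sample structure assumed by summary-data MR.
#' Variants monomorphic in either subsample are excluded with a warning.
#'
#' @param cohort An `ecg_cohort`.
#' @param split_fraction Fraction of individuals allocated to the exposure
#'   subsample, in (0,1); the remainder forms the outcome subsample.
#' @param orient If `TRUE` (default), pairs are oriented so every exposure
#'   beta is coded to the interval-lengthening allele (the harmonisation
#'   contract downstream estimators assume).
#' @return A `summary_pairs` data frame: `id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta_exposure`, `se_exposure`, `p_exposure`,
#'   `beta_outcome`, `se_outcome`, `p_outcome`, plus attribute `excluded`.
#' @export
make_summary_pairs <- function(cohort, split_fraction = 0.5, orient = TRUE) {
  stopifnot(inherits(cohort, "ecg_cohort"),
            split_fraction > 0, split_fraction < 1)
  n <- length(cohort$exposure)
  n1 <- floor(n * split_fraction)
  i1 <- seq_len(n1)
  i2 <- seq.int(n1 + 1L, n)
  g1 <- cohort$genotypes[i1, , drop = FALSE]
  g2 <- cohort$genotypes[i2, , drop = FALSE]
  mono <- apply(g1, 2, stats::var) == 0 | apply(g2, 2, stats::var) == 0
  if (any(mono)) {
    warning(sprintf("excluding %d monomorphic variant(s): %s",
                    sum(mono), paste(colnames(g1)[mono], collapse = ", ")))
    g1 <- g1[, !mono, drop = FALSE]
    g2 <- g2[, !mono, drop = FALSE]
  }
  expo <- linear_scan(g1, cohort$exposure[i1])
  outc <- logistic_scan(g2, cohort$outcome[i2])
  v <- cohort$variants[match(colnames(g1), cohort$variants$id), ]
  out <- data.frame(
    id = colnames(g1),
    effect_allele = v$effect_allele,
    other_allele = v$other_allele,
    eaf = colMeans(g1) / 2,
    beta_exposure = expo$beta,
    se_exposure = expo$se,
    p_exposure = 2 * stats::pnorm(-abs(expo$beta / expo$se)),
    beta_outcome = outc$beta,
    se_outcome = outc$se,
    p_outcome = 2 * stats::pnorm(-abs(outc$beta / outc$se)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (orient) {
    flip <- out$beta_exposure < 0
    out[flip, c("beta_exposure", "beta_outcome")] <-
      -out[flip, c("beta_exposure", "beta_outcome")]
    ea <- out$effect_allele
    out$effect_allele[flip] <- out$other_allele[flip]
    out$other_allele[flip] <- ea[flip]
    out$eaf[flip] <- 1 - out$eaf[flip]
  }
  structure(out, excluded = colnames(cohort$genotypes)[mono],
            class = c("summary_pairs", "data.frame"))
}

# Closed-form simple linear regression of y on each column of g.
linear_scan <- function(g, y) {
  n <- length(y)
  gc <- sweep(g, 2, colMeans(g))
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  beta <- colSums(gc * yc) / sxx
  rss <- sum(yc^2) - beta^2 * sxx  # vectorised residual SS per variant
  se <- sqrt(pmax(rss, 0) / ((n - 2) * sxx))
  list(beta = beta, se = se)
}

# Vectorised Newton-Raphson for per-variant logistic regression of y on
# (1, g_j), all variants at once. Matches glm() coefficients and Fisher
# standard errors; exists because fitting thousands of single-variant
# glm()s dominates simulation runtime.
logistic_scan <- function(g, y, max_iter = 25L, tol = 1e-10) {
  n <- length(y)
  m <- ncol(g)
  a <- rep(stats::qlogis(mean(y)), m)
  b <- numeric(m)
  sy <- sum(y)
  gy <- colSums(g * y)
  for (it in seq_len(max_iter)) {
    eta <- sweep(g * rep(b, each = n), 2, a, "+")
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    s0 <- colSums(w); s1 <- colSums(w * g); s2 <- colSums(w * g^2)
    u0 <- sy - colSums(mu)
    u1 <- gy - colSums(mu * g)
    det <- s0 * s2 - s1^2
    da <- (s2 * u0 - s1 * u1) / det
    db <- (s0 * u1 - s1 * u0) / det
    a <- a + da
    b <- b + db
    if (max(abs(da), abs(db)) < tol) break
  }
  eta <- sweep(g * rep(b, each = n), 2, a, "+")
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  s0 <- colSums(w); s1 <- colSums(w * g); s2 <- colSums(w * g^2)
  det <- s0 * s2 - s1^2
  list(beta = b, se = sqrt(s0 / det))
}
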