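#' Reverse-direction summary pairs from a cohort
#'
#' Builds the summary pairs for a bidirectional analysis: the per-variant
#' *exposure* side is the log odds ratio on the binary outcome (logistic
#' regression of outcome on dosage in the first subsample) and the
#' *outcome* side is the effect on the ECG interval in ms (linear
#' regression in the second, disjoint subsample). Used with an
#' outcome-liability instrument set to ask whether genetic risk of the
#' arrhythmia shifts the interval, rather than the other way round.
#'
#' @param cohort An `ecg_cohort` whose variants instrument the outcome
#'   liability.
#' @param split_fraction Fraction allocated to the liability (exposure)
#'   subsample.
#' @return A `summary_pairs` data frame oriented to positive exposure
#'   betas; exposure columns are log-OR units, outcome columns ms.
#' @export
make_reverse_pairs <- function(cohort, split_fraction = 0.5) {
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
    warning(sprintf("excluding %d monomorphic variant(s)", sum(mono)))
    g1 <- g1[, !mono, drop = FALSE]
    g2 <- g2[, !mono, drop = FALSE]
  }
  liab <- logistic_scan(g1, cohort$outcome[i1])
  intv <- linear_scan(g2, cohort$exposure[i2])
  v <- cohort$variants[match(colnames(g1), cohort$variants$id), ]
  out <- data.frame(
    id = colnames(g1),
    effect_allele = v$effect_allele,
    other_allele = v$other_allele,
    eaf = colMeans(g1) / 2,
    beta_exposure = liab$beta,
    se_exposure = liab$se,
    p_exposure = 2 * stats::pnorm(-abs(liab$beta / liab$se)),
    beta_outcome = intv$beta,
    se_outcome = intv$se,
    p_outcome = 2 * stats::pnorm(-abs(intv$beta / intv$se)),
    stringsAsFactors = FALSE
  )
  flip <- out$beta_exposure < 0
  out[flip, c("beta_exposure", "beta_outcome")] <-
    -out[flip, c("beta_exposure", "beta_outcome")]
  ea <- out$effect_allele
  out$effect_allele[flip] <- out$other_allele[flip]
  out$other_allele[flip] <- ea[flip]
  out$eaf[flip] <- 1 - out$eaf[flip]
  rownames(out) <- NULL
  structure(out, class = c("summary_pairs", "data.frame"))
}

#' Pipeline configuration
#'
#' Resolves the configuration for an end-to-end run: either a simulation
#' scenario (a [sim_config()]) or paths to cohort files, the analysis
#' roster, stochastic-method settings and the master seed. Fully
#' serialisable; [run_pipeline()] writes the resolved configuration next
#' to its outputs so a run can be reproduced exactly.
#'
#' @param sim A `sim_config` describing the synthetic cohort (ignored when
#'   `input_dir` is given).
#' @param input_dir Optional directory holding `genotypes.tsv`,
#'   `phenotypes.tsv`, `variants.tsv` as written by [write_cohort()].
#' @param score_name Label for the ECG score (e.g. `"PR interval"`).
#' @param display_constant Additive ms constant for quintile displays.
#' @param split_fraction Two-sample split for summary statistics.
#' @param ion_channel_genes Gene list for the channel-pathway subset.
#' @param secondary_outcomes Named list of additional binary outcomes,
#'   each a list with `causal_beta` and `prevalence`, simulated from the
#'   same exposure (lone-arrhythmia / other-tachycardia analogues).
#' @param bidirectional List describing the outcome-liability instrument
#'   world used for the reverse-direction check: `n_variants` in the
#'   liability panel, `liability_logor` (per-allele direct log-odds effect
#'   on the outcome) and `reverse_ms_per_logodds` (ms shift of the
#'   interval per log-odds of liability; 0 means no reverse causal path).
#' @param n_boot,n_sim Bootstrap and simulation draws for the stochastic
#'   estimators.
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            input_dir = NULL,
                            score_name = "PR interval",
                            display_constant = 93.5,
                            split_fraction = 0.5,
                            ion_channel_genes = c("SCN5A", "SCN10A",
                                                  "KCNQ1", "KCNJ2"),
                            secondary_outcomes = list(),
                            bidirectional = list(n_variants = 12L,
                                                 liability_logor = 0.15,
                                                 reverse_ms_per_logodds = 0),
                            n_boot = 1000L,
                            n_sim = 1000L,
                            seed = 1L,
                            out_dir = NULL) {
  structure(list(sim = sim, input_dir = input_dir, score_name = score_name,
                 display_constant = display_constant,
                 split_fraction = split_fraction,
                 ion_channel_genes = ion_channel_genes,
                 secondary_outcomes = secondary_outcomes,
                 bidirectional = bidirectional,
                 n_boot = as.integer(n_boot), n_sim = as.integer(n_sim),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a scenario file whose top-level keys mirror the arguments of
#' [pipeline_config()] and, under `sim`, those of [sim_config()] (with
#' `variants` either a file path or the arguments of
#' [simulate_variant_table()]).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim
  if (!is.null(sim_args)) {
    if (is.character(sim_args$variants))
      sim_args$variants <- read_variant_table(sim_args$variants)
    else if (is.list(sim_args$variants))
      sim_args$variants <- do.call(simulate_variant_table, sim_args$variants)
    raw$sim <- do.call(sim_config, sim_args)
  }
  do.call(pipeline_config, raw)
}

log_stage <- function(log, stage, operation, detail = "") {
  rbind(log, data.frame(stage = stage, operation = operation,
                        detail = detail, stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis sequence on one cohort: score construction
#' and strength report; score-interval linear association with the
#' quintile display; per-5 ms logistic associations for the primary and
#' any secondary binary outcomes; quintile contrasts with floated
#' variances; the ion-channel-subset estimate; the two-sample sensitivity
#' table (IVW fixed/random, weighted median/mode, Egger slope and
#' intercept, MR-PRESSO-corrected); a fixed-effects meta-analysis of the
#' cohort estimate with the two-sample IVW (the external-replication
#' analogue); and a bidirectional check using reverse-direction pairs.
#' Every table records the operation that produced it in the run log, and
#' a fixed seed reproduces the whole bundle.
#'
#' @param config A `pipeline_config`.
#' @return An `ecgmr_run` bundle: list with `config`, `log`, `cohort`
#'   summary, `strength`, `score_interval`, `quintile_display`,
#'   `per5ms` (per-outcome associations), `floated`, `ion_channel`,
#'   `sensitivity`, `meta`, `bidirectional`, `funnel`. Tables are written
#'   under `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- data.frame(stage = character(), operation = character(),
                    detail = character(), stringsAsFactors = FALSE)
  fail <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)

  # --- cohort ---------------------------------------------------------
  cohort <- tryCatch({
    if (!is.null(config$input_dir)) {
      gp <- file.path(config$input_dir, "genotypes.tsv")
      pp <- file.path(config$input_dir, "phenotypes.tsv")
      vp <- file.path(config$input_dir, "variants.tsv")
      for (f in c(gp, pp, vp))
        if (!file.exists(f))
          stop("required input file does not exist: ", f)
      geno <- as.matrix(utils::read.delim(gp, check.names = FALSE))
      phen <- utils::read.delim(pp)
      vars <- read_variant_table(vp)
      covs <- phen[, setdiff(names(phen), c("id", "exposure", "outcome")),
                   drop = FALSE]
      structure(list(genotypes = geno, exposure = phen$exposure,
                     outcome = phen$outcome, covariates = covs,
                     confounder = NULL, variants = vars,
                     config = config$sim),
                class = "ecg_cohort")
    } else {
      simulate_cohort(config$sim)
    }
  }, error = function(e) fail("cohort", e))
  log <- log_stage(log, "cohort",
                   if (is.null(config$input_dir)) "simulate_cohort"
                   else "read_cohort",
                   sprintf("n=%d m=%d seed=%d", length(cohort$exposure),
                           ncol(cohort$genotypes), config$seed))

  weights <- stats::setNames(cohort$variants$beta, cohort$variants$id)
  score <- build_score(cohort$genotypes, weights)
  log <- log_stage(log, "scores", "build_score",
                   sprintf("%d variants", score$n_variants))

  strength <- strength_report(score, cohort$exposure,
                              n_outcome = length(cohort$outcome),
                              case_fraction = mean(cohort$outcome))
  log <- log_stage(log, "scores", "strength_report",
                   sprintf("r2=%.4f F=%.1f power=%.3f", strength$r2,
                           strength$f_stat, strength$power))

  # --- score vs interval (first-stage display) ------------------------
  score_interval <- tryCatch(
    linear_assoc(score, cohort$exposure, cohort$covariates,
                 outcome_label = config$score_name),
    error = function(e) fail("score_interval", e))
  quint <- assign_quintiles(score, reference = cohort$outcome == 0L)
  qdisp <- quintile_display(score, quint, config$display_constant)
  log <- log_stage(log, "cohort_assoc", "linear_assoc", config$score_name)
  log <- log_stage(log, "cohort_assoc", "quintile_display",
                   sprintf("constant=%.1f ms", config$display_constant))

  # --- per-5ms logistic associations ----------------------------------
  outcomes <- list(primary = cohort$outcome)
  if (length(config$secondary_outcomes)) {
    set.seed(config$seed + 101L)
    for (nm in names(config$secondary_outcomes)) {
      so <- config$secondary_outcomes[[nm]]
      cfg2 <- cohort$config
      cfg2$causal_beta <- so$causal_beta
      cfg2$baseline_prevalence <- so$prevalence
      outcomes[[nm]] <- as.integer(
        simulate_outcome(cohort$exposure, cohort$genotypes, cfg2,
                         confounder = cohort$confounder))
    }
  }
  per5ms <- lapply(names(outcomes), function(nm) {
    res <- tryCatch(
      logistic_assoc(score, outcomes[[nm]], cohort$covariates,
                     outcome_label = nm),
      error = function(e) fail(paste0("logistic_assoc:", nm), e))
    scale_per_5ms(res)
  })
  names(per5ms) <- names(outcomes)
  for (nm in names(per5ms))
    log <- log_stage(log, "cohort_assoc", "logistic_assoc+scale_per_5ms", nm)

  # --- quintile contrasts with floated variances ----------------------
  floated <- tryCatch(
    quintile_contrasts(score, cohort$outcome, cohort$covariates,
                       quintiles = quint),
    error = function(e) fail("quintile_contrasts", e))
  log <- log_stage(log, "cohort_assoc", "quintile_contrasts",
                   sprintf("max_rel_err=%.3f", attr(floated, "max_rel_error")))

  # --- ion-channel subset ---------------------------------------------
  ion <- NULL
  if ("gene" %in% names(cohort$variants)) {
    chan <- suppressWarnings(
      ion_channel_subset(cohort$variants, config$ion_channel_genes))
    if (nrow(chan) >= 2L) {
      chan_score <- build_score(cohort$genotypes,
                                stats::setNames(chan$beta, chan$id))
      ion <- scale_per_5ms(
        logistic_assoc(chan_score, cohort$outcome, cohort$covariates,
                       outcome_label = "primary (ion-channel subset)"))
      log <- log_stage(log, "instruments", "ion_channel_subset",
                       sprintf("%d variants", nrow(chan)))
    }
  }

  # --- two-sample summary MR ------------------------------------------
  pairs <- tryCatch(
    suppressWarnings(make_summary_pairs(cohort, config$split_fraction)),
    error = function(e) fail("make_summary_pairs", e))
  log <- log_stage(log, "synthetic_data", "make_summary_pairs",
                   sprintf("split=%.2f J=%d", config$split_fraction,
                           nrow(pairs)))
  sens <- tryCatch(
    mr_sensitivity(pairs, n_boot = config$n_boot, n_sim = config$n_sim,
                   seed = config$seed + 202L, per_5ms = TRUE),
    error = function(e) fail("mr_sensitivity", e))
  log <- log_stage(log, "summary_mr", "mr_sensitivity",
                   paste(sens$method, collapse = ","))

  ivw5 <- scale_per_5ms(mr_ivw(pairs, "fixed"))
  meta <- mr_meta_fixed(list(per5ms$primary, ivw5))
  log <- log_stage(log, "summary_mr", "mr_meta_fixed",
                   "cohort estimate + two-sample IVW")

  # --- bidirectional ---------------------------------------------------
  # a *separate* outcome-liability instrument panel: variants act on the
  # outcome directly; the interval responds only through the configured
  # reverse path (0 ms per log-odds by default, i.e. no reverse causation)
  bidir <- tryCatch({
    bd <- config$bidirectional
    v_af <- simulate_variant_table(bd$n_variants, seed = config$seed + 303L)
    sgn <- sign(v_af$beta)
    v_af$beta <- bd$reverse_ms_per_logodds * bd$liability_logor * sgn
    cfg_rev <- sim_config(
      n_individuals = length(cohort$exposure),
      variants = v_af, target_r2 = NULL, causal_beta = 0,
      baseline_prevalence = config$sim$baseline_prevalence,
      mean_exposure = config$sim$mean_exposure,
      sd_exposure = config$sim$sd_exposure,
      pleiotropy = bd$liability_logor * sgn,
      n_pcs = 0, seed = config$seed + 304L)
    co_rev <- simulate_cohort(cfg_rev)
    rev_pairs <- suppressWarnings(
      make_reverse_pairs(co_rev, config$split_fraction))
    mr_bidirectional(rev_pairs, forward = mr_ivw(pairs, "fixed"))
  }, error = function(e) fail("bidirectional", e))
  log <- log_stage(log, "summary_mr", "mr_bidirectional",
                   sprintf("liability panel J=%d, loop gain=%.4g",
                           config$bidirectional$n_variants,
                           bidir$notes$loop_gain))

  fun <- funnel_data(pairs)
  log <- log_stage(log, "summary_mr", "funnel_data", "")

  bundle <- structure(list(
    config = config, log = log,
    cohort_summary = data.frame(n = length(cohort$exposure),
                                m = ncol(cohort$genotypes),
                                cases = sum(cohort$outcome),
                                prevalence = mean(cohort$outcome)),
    strength = strength,
    score_interval = score_interval,
    quintile_display = qdisp,
    per5ms = per5ms,
    floated = floated,
    ion_channel = ion,
    sensitivity = sens,
    meta = meta,
    bidirectional = bidir,
    funnel = fun
  ), class = "ecgmr_run")

  if (!is.null(config$out_dir)) write_run_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.ecgmr_run <- function(x, ...) {
  cat("=== ecgmr pipeline run:", x$config$score_name, "===\n\n")
  print(x$cohort_summary, row.names = FALSE)
  cat("\n-- instrument strength --\n")
  print(x$strength)
  cat("\n-- score vs measured interval --\n")
  print(x$score_interval)
  cat("\n-- per-5ms associations --\n")
  for (r in x$per5ms) print(r)
  if (!is.null(x$ion_channel)) print(x$ion_channel)
  cat("\n-- quintile contrasts (floated variances) --\n")
  print(x$floated)
  cat("\n-- sensitivity analyses (per 5 ms) --\n")
  print(x$sensitivity, row.names = FALSE, digits = 4)
  cat("\n-- meta-analysis (cohort + two-sample IVW) --\n")
  print(x$meta)
  cat("\n-- bidirectional --\n")
  print(x$bidirectional)
  invisible(x)
}

assoc_row <- function(r, label) {
  data.frame(label = label, beta = r$beta, se = r$se, or = exp(r$beta),
             ci_low = exp(r$ci_low), ci_high = exp(r$ci_high), p = r$p,
             scale = r$scale, significance = r$significance,
             stringsAsFactors = FALSE)
}

#' Write a run bundle to tab-separated tables
#'
#' Each table is written with a schema-version header line
#' (`#ecgmr schema=1 table=<name>`), and the resolved configuration and
#' run log are stored alongside, so a bundle directory is a complete,
#' reproducible record of the run.
#'
#' @param bundle An `ecgmr_run`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_run_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ecgmr_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    con <- file(p, "w")
    writeLines(sprintf("#ecgmr\tschema=1\ttable=%s", name), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    paths <<- c(paths, p)
  }
  put(bundle$cohort_summary, "cohort_summary")
  put(as.data.frame(bundle$strength), "strength")
  put(assoc_row(bundle$score_interval, "score_vs_interval"),
      "score_interval")
  put(bundle$quintile_display, "quintile_display")
  put(do.call(rbind, Map(assoc_row, bundle$per5ms, names(bundle$per5ms))),
      "per5ms")
  put(as.data.frame(bundle$floated), "floated_quintiles")
  if (!is.null(bundle$ion_channel))
    put(assoc_row(bundle$ion_channel, "ion_channel"), "ion_channel")
  put(bundle$sensitivity, "sensitivity")
  put(data.frame(method = bundle$meta$method, beta = bundle$meta$beta,
                 se = bundle$meta$se, p = bundle$meta$p,
                 Q = bundle$meta$Q, Q_df = bundle$meta$Q_df),
      "meta")
  put(data.frame(method = bundle$bidirectional$method,
                 beta = bundle$bidirectional$beta,
                 se = bundle$bidirectional$se,
                 p = bundle$bidirectional$p,
                 loop_gain = bundle$bidirectional$notes$loop_gain),
      "bidirectional")
  put(bundle$funnel, "funnel")
  put(bundle$log, "run_log")
  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg <- bundle$config
    cfg_ser <- list(score_name = cfg$score_name,
                    display_constant = cfg$display_constant,
                    split_fraction = cfg$split_fraction,
                    ion_channel_genes = cfg$ion_channel_genes,
                    n_boot = cfg$n_boot, n_sim = cfg$n_sim,
                    seed = cfg$seed,
                    sim = list(n_individuals = cfg$sim$n_individuals,
                               n_variants = nrow(cfg$sim$variants),
                               target_r2 = cfg$sim$target_r2,
                               causal_beta = cfg$sim$causal_beta,
                               baseline_prevalence =
                                 cfg$sim$baseline_prevalence,
                               mean_exposure = cfg$sim$mean_exposure,
                               sd_exposure = cfg$sim$sd_exposure,
                               seed = cfg$sim$seed))
    yaml::write_yaml(cfg_ser, file.path(dir, "resolved_config.yaml"))
    paths <- c(paths, file.path(dir, "resolved_config.yaml"))
  }
  invisible(paths)
}

#' Read a bundle table written by [write_run_bundle()]
#'
#' @param path Path to a `.tsv` written with the schema-version header.
#' @return The data frame, with attribute `schema`.
#' @export
read_bundle_table <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#ecgmr"))
    stop(path, " is not an ecgmr bundle table (missing schema header)")
  out <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  attr(out, "schema") <- header
  out
}
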