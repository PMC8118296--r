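#' Genome-wide significance filter
#'
#' Retains variants whose exposure p-value falls strictly below the
#' threshold (the conventional genome-wide level, 5e-8, by default),
#' preserving input order.
#'
#' @param variants Variant table with columns `id` and `p` (exposure
#'   association p-value).
#' @param threshold Significance threshold in (0,1).
#' @return The filtered variant table; warns if empty.
#' @export
gw_significance_filter <- function(variants, threshold = 5e-8) {
  stopifnot(is.data.frame(variants), "p" %in% names(variants),
            threshold > 0, threshold < 1)
  keep <- variants$p < threshold
  out <- variants[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no variant passes the significance threshold")
  rownames(out) <- NULL
  out
}

#' Greedy linkage-disequilibrium clumping
#'
#' Prunes a variant list to an approximately independent set: candidates
#' are visited in ascending p-value order, and a candidate is discarded
#' when any already-retained variant on the same chromosome lies within the
#' physical window and is correlated with it at `r2 >= r2_threshold`.
#' Defaults match standard instrument-selection practice (r2 < 0.01 within
#' a +/- 250 kb window). A missing r2 for an in-window pair is treated as
#' r2 = 1 (the pair is assumed dependent) and logged.
#'
#' @param variants Variant table with columns `id`, `chr`, `pos`, `p`.
#' @param ld Pairwise r2 provider: either a symmetric matrix with variant
#'   ids as dimnames, or a function `f(id1, id2)` returning a single r2
#'   (NA allowed).
#' @param r2_threshold Variants correlated at or above this r2 cannot both
#'   be retained.
#' @param window_bp Physical window; only same-chromosome pairs with
#'   `|pos1 - pos2| <= window_bp` are tested.
#' @return The retained variant table, in the original input order, with
#'   attribute `clump_log` (a data frame of removals and missing-LD events).
#' @export
ld_clump <- function(variants, ld, r2_threshold = 0.01, window_bp = 250000) {
  stopifnot(is.data.frame(variants),
            all(c("id", "chr", "pos", "p") %in% names(variants)))
  r2_of <- if (is.function(ld)) {
    ld
  } else {
    stopifnot(is.matrix(ld))
    function(i, j) {
      if (i %in% rownames(ld) && j %in% colnames(ld)) ld[i, j] else NA_real_
    }
  }
  ord <- order(variants$p)
  kept <- integer(0)
  log <- list()
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      if (variants$chr[k] != variants$chr[i]) next
      if (abs(variants$pos[k] - variants$pos[i]) > window_bp) next
      r2 <- r2_of(variants$id[i], variants$id[k])
      if (is.na(r2)) {
        log[[length(log) + 1L]] <- data.frame(
          id = variants$id[i], against = variants$id[k],
          event = "missing_ld_treated_dependent", r2 = NA_real_)
        r2 <- 1
      }
      if (r2 >= r2_threshold) {
        log[[length(log) + 1L]] <- data.frame(
          id = variants$id[i], against = variants$id[k],
          event = "removed", r2 = r2)
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- variants[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "clump_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(id = character(), against = character(),
               event = character(), r2 = numeric())
  out
}

strand_complement <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns per-variant outcome statistics to the exposure coding, resolving
#' swapped alleles and strand-complement reporting, then re-orients every
#' pair to the interval-lengthening allele so that all exposure betas are
#' non-negative (sign flips are applied jointly to both betas, and the
#' effect-allele frequency is complemented). Palindromic variants (A/T or
#' C/G) with effect-allele frequency inside the ambiguity window are
#' dropped, as are variants absent from the outcome data or with
#' irreconcilable allele sets; every drop is logged with a machine-readable
#' reason.
#'
#' @param exposure Variant table with columns `id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se` (and optionally `p`).
#' @param outcome_stats Data frame with columns `id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`.
#' @param palindromic_window Effect-allele frequency interval within which
#'   a palindromic variant is considered strand-ambiguous and dropped.
#' @return A `summary_pairs` data frame (see [make_summary_pairs()]) with
#'   attribute `harmonise_log`, a data frame of per-variant actions.
#' @export
harmonise <- function(exposure, outcome_stats,
                      palindromic_window = c(0.42, 0.58)) {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome_stats))
  log <- list()
  note <- function(id, action, reason = "") {
    log[[length(log) + 1L]] <<- data.frame(id = id, action = action,
                                           reason = reason)
  }
  rows <- list()
  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    j <- match(ex$id, outcome_stats$id)
    if (is.na(j)) { note(ex$id, "dropped", "not_in_outcome"); next }
    if (is_palindromic(ex$effect_allele, ex$other_allele) &&
        ex$eaf >= palindromic_window[1] && ex$eaf <= palindromic_window[2]) {
      note(ex$id, "dropped", "palindromic_ambiguous")
      next
    }
    ou <- outcome_stats[j, ]
    b_out <- NA_real_
    if (ou$effect_allele == ex$effect_allele &&
        ou$other_allele == ex$other_allele) {
      b_out <- ou$beta
      note(ex$id, "kept", "direct")
    } else if (ou$effect_allele == ex$other_allele &&
               ou$other_allele == ex$effect_allele) {
      b_out <- -ou$beta
      note(ex$id, "kept", "allele_swap")
    } else {
      cea <- strand_complement(ou$effect_allele)
      coa <- strand_complement(ou$other_allele)
      if (cea == ex$effect_allele && coa == ex$other_allele) {
        b_out <- ou$beta
        note(ex$id, "kept", "strand_flip")
      } else if (cea == ex$other_allele && coa == ex$effect_allele) {
        b_out <- -ou$beta
        note(ex$id, "kept", "strand_flip_swap")
      } else {
        note(ex$id, "dropped", "allele_mismatch")
        next
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = ex$id,
      effect_allele = ex$effect_allele,
      other_allele = ex$other_allele,
      eaf = ex$eaf,
      beta_exposure = ex$beta,
      se_exposure = ex$se,
      p_exposure = if ("p" %in% names(ex)) ex$p else NA_real_,
      beta_outcome = b_out,
      se_outcome = ou$se,
      p_outcome = 2 * stats::pnorm(-abs(b_out / ou$se)),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), effect_allele = character(),
               other_allele = character(), eaf = numeric(),
               beta_exposure = numeric(), se_exposure = numeric(),
               p_exposure = numeric(), beta_outcome = numeric(),
               se_outcome = numeric(), p_outcome = numeric())
  # orient to the interval-lengthening allele: beta_exposure >= 0
  flip <- out$beta_exposure < 0
  if (any(flip)) {
    out[flip, c("beta_exposure", "beta_outcome")] <-
      -out[flip, c("beta_exposure", "beta_outcome")]
    ea <- out$effect_allele
    out$effect_allele[flip] <- out$other_allele[flip]
    out$other_allele[flip] <- ea[flip]
    out$eaf[flip] <- 1 - out$eaf[flip]
  }
  rownames(out) <- NULL
  structure(out,
            harmonise_log = do.call(rbind, log),
            class = c("summary_pairs", "data.frame"))
}

#' Restrict a variant set to ion-channel gene annotations
#'
#' Retains variants whose `gene` annotation belongs to the supplied list of
#' ion-channel loci (for example SCN5A, SCN10A, KCNQ1, KCNJ2); weights are
#' untouched. Used to test whether score-outcome effects are carried by
#' electrical (channel) pathways specifically.
#'
#' @param variants Variant table with a `gene` column.
#' @param gene_list Character vector of gene symbols to retain.
#' @return The subset table; warns when fewer than 2 variants remain, since
#'   ratio-based estimators cannot be built on a smaller set.
#' @export
ion_channel_subset <- function(variants,
                               gene_list = c("SCN5A", "SCN10A",
                                             "KCNQ1", "KCNJ2")) {
  stopifnot(is.data.frame(variants), "gene" %in% names(variants))
  out <- variants[variants$gene %in% gene_list, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) < 2L)
    warning("fewer than 2 variants in the ion-channel subset; ",
            "ratio-based estimators will decline to fit")
  out
}

#' Read and write variant-weight and summary-statistic tables
#'
#' Tab-separated readers/writers for the two interchange schemas used
#' throughout the package: the variant-weight table (`id`, `chr`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`, optionally
#' `gene`) and the GWAS-SSF-like summary-statistics layout (`variant_id`,
#' `chromosome`, `base_pair_location`, `effect_allele`, `other_allele`,
#' `effect_allele_frequency`, `beta`, `standard_error`, `p_value`, `n`).
#'
#' @param path File path.
#' @param variants,stats Data frame to write.
#' @return The data frame read, or (invisibly) the path written.
#' @name variant_io
NULL

#' @rdname variant_io
#' @export
read_variant_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chr = "character"))
  need <- c("id", "chr", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "p")
  missing <- setdiff(need, names(out))
  if (length(missing))
    stop("variant table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  out
}

#' @rdname variant_io
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname variant_io
#' @export
read_summary_stats <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "other_allele",
            "beta", "standard_error")
  missing <- setdiff(need, names(out))
  if (length(missing))
    stop("summary-statistics file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  data.frame(id = out$variant_id,
             effect_allele = out$effect_allele,
             other_allele = out$other_allele,
             eaf = if ("effect_allele_frequency" %in% names(out))
               out$effect_allele_frequency else NA_real_,
             beta = out$beta,
             se = out$standard_error,
             p = if ("p_value" %in% names(out)) out$p_value else NA_real_,
             n = if ("n" %in% names(out)) out$n else NA_real_,
             stringsAsFactors = FALSE)
}

#' @rdname variant_io
#' @export
write_summary_stats <- function(stats, path) {
  ssf <- data.frame(
    variant_id = stats$id,
    chromosome = if ("chr" %in% names(stats)) stats$chr else NA,
    base_pair_location = if ("pos" %in% names(stats)) stats$pos else NA,
    effect_allele = stats$effect_allele,
    other_allele = stats$other_allele,
    effect_allele_frequency = stats$eaf,
    beta = stats$beta,
    standard_error = stats$se,
    p_value = if ("p" %in% names(stats)) stats$p else NA,
    n = if ("n" %in% names(stats)) stats$n else NA
  )
  utils::write.table(ssf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort to tab-separated files
#'
#' Emits three files under `dir`: `genotypes.tsv` (individuals x variants,
#' header = variant ids), `phenotypes.tsv` (id, exposure, outcome,
#' covariates) and `variants.tsv` (the weight table).
#'
#' @param cohort An `ecg_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ecg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gpath <- file.path(dir, "genotypes.tsv")
  ppath <- file.path(dir, "phenotypes.tsv")
  vpath <- file.path(dir, "variants.tsv")
  utils::write.table(cohort$genotypes, gpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  phen <- cbind(data.frame(id = seq_along(cohort$exposure),
                           exposure = cohort$exposure,
                           outcome = cohort$outcome),
                cohort$covariates)
  utils::write.table(phen, ppath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_variant_table(cohort$variants, vpath)
  invisible(c(genotypes = gpath, phenotypes = ppath, variants = vpath))
}
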