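#' Configuration of the two-step interaction screen
#'
#' @param candidate_p Suggestive-association threshold for candidate
#'   selection (default 1e-5).
#' @param candidate_maf Minimum minor allele frequency for candidates
#'   (default 0.01, strict).
#' @param gwas_significance Genome-wide significance threshold (default
#'   5e-8).
#' @param bonferroni_alpha Family-wise alpha divided by the locus count
#'   (default 0.05).
#' @param clump_r2 LD threshold for clumping (default 0.1).
#' @param window_bp Clumping window (default 250 kb).
#' @param merge_gap_bp Span-to-span merge gap (default 250 kb).
#' @param pad_bp Locus extension (default 250 kb).
#' @param spa_switch_z Saddlepoint hybrid switch (default 2).
#' @param models Model presets to run (subset of model1..model4).
#' @return Object of class `screen_config`.
#' @export
screen_config <- function(candidate_p = 1e-5, candidate_maf = 0.01,
                          gwas_significance = 5e-8, bonferroni_alpha = 0.05,
                          clump_r2 = 0.1, window_bp = 250000L,
                          merge_gap_bp = 250000L, pad_bp = 250000L,
                          spa_switch_z = 2, models = "model1") {
  stopifnot(candidate_p > 0, candidate_p < 1, candidate_maf > 0,
            bonferroni_alpha > 0, bonferroni_alpha < 1,
            clump_r2 > 0, clump_r2 < 1,
            window_bp > 0, merge_gap_bp > 0, pad_bp > 0,
            all(models %in% paste0("model", 1:4)))
  structure(list(candidate_p = candidate_p, candidate_maf = candidate_maf,
                 gwas_significance = gwas_significance,
                 bonferroni_alpha = bonferroni_alpha, clump_r2 = clump_r2,
                 window_bp = as.integer(window_bp),
                 merge_gap_bp = as.integer(merge_gap_bp),
                 pad_bp = as.integer(pad_bp), spa_switch_z = spa_switch_z,
                 models = models), class = "screen_config")
}

#' Select candidate variants from overall and subgroup GWAS
#'
#' Union of variants reaching the suggestive threshold in the overall scan
#' or either exposure-stratified scan, restricted to common variants
#' (MAF > `candidate_maf`). Each candidate is tagged with every discovery
#' source reaching the threshold.
#'
#' @param overall,users,nonusers GWAS result tables over the same variant
#'   universe (see [run_gwas()]).
#' @param cfg A [screen_config()].
#' @return Data frame: `id`, `chrom`, `pos`, `maf`, `p_overall`,
#'   `p_users`, `p_nonusers`, `discovery_source` (comma-joined tags).
#'   Zero rows (with a warning) when no variant qualifies.
#' @export
select_candidates <- function(overall, users, nonusers, cfg = screen_config()) {
  if (!identical(overall$id, users$id) || !identical(overall$id, nonusers$id)) {
    stop("the three GWAS tables must cover the same variants in the same order")
  }
  maf <- pmin(overall$af, 1 - overall$af)
  hit <- function(tab) !is.na(tab$p) & tab$p < cfg$candidate_p
  h_o <- hit(overall); h_u <- hit(users); h_n <- hit(nonusers)
  sel <- (h_o | h_u | h_n) & maf > cfg$candidate_maf
  if (!any(sel)) {
    warning("no candidate variants reach p < ", cfg$candidate_p,
            " at MAF > ", cfg$candidate_maf)
  }
  src <- vapply(which(sel), function(i) {
    paste(c("overall", "users", "nonusers")[c(h_o[i], h_u[i], h_n[i])],
          collapse = ",")
  }, "")
  data.frame(id = overall$id[sel], chrom = overall$chrom[sel],
             pos = overall$pos[sel], maf = maf[sel],
             p_overall = overall$p[sel], p_users = users$p[sel],
             p_nonusers = nonusers$p[sel],
             discovery_source = src, stringsAsFactors = FALSE)
}

#' Locus-level Bonferroni threshold
#'
#' @param n_loci Number of independent candidate loci (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_loci`.
#' @export
bonferroni_threshold <- function(n_loci, alpha = 0.05) {
  stopifnot(n_loci >= 1)
  alpha / n_loci
}

# shared core: interaction fit for an arbitrary dosage vector
test_interaction_core <- function(dosage, exposure, outcome, model, cohort,
                                  variant_id = NA_character_) {
  d <- dosage
  d[is.na(d)] <- mean(d, na.rm = TRUE)
  cohort$.g <- d
  e <- cohort[[exposure]]
  if (!all(stats::na.omit(e) %in% c(0, 1))) {
    e <- (e - mean(e, na.rm = TRUE)) / stats::sd(e, na.rm = TRUE)
  }
  cohort$.e <- e
  terms <- c(model_covariates(model), ".e", ".g", ".g:.e")
  res <- tryCatch({
    fit <- fit_cox(cohort, terms, outcome)
    int_term <- intersect(c(".g:.e", ".e:.g"), names(fit$beta))[1]
    w <- wald_test(fit, int_term)
    data.frame(variant_id = variant_id, outcome = outcome,
               exposure = exposure, model = model,
               beta_int = w$beta, se = w$se, z = w$z, p_int = w$p,
               hr_int = w$hr, hr_int_lo = w$hr_lo, hr_int_hi = w$hr_hi,
               converged = fit$converged, stringsAsFactors = FALSE)
  }, error = function(e2) {
    data.frame(variant_id = variant_id, outcome = outcome,
               exposure = exposure, model = model,
               beta_int = NA_real_, se = NA_real_, z = NA_real_,
               p_int = NA_real_, hr_int = NA_real_, hr_int_lo = NA_real_,
               hr_int_hi = NA_real_, converged = FALSE,
               stringsAsFactors = FALSE)
  })
  res
}

#' Test a SNP-by-exposure interaction in a Cox model
#'
#' Fits the requested covariate preset plus exposure, additive dosage and
#' the dosage-by-exposure product term; the interaction p-value is the
#' Wald test on the product coefficient. A continuous exposure (e.g. a
#' circulating biomarker concentration) is standardized to mean 0, SD 1
#' before forming the product. Non-convergence yields a flagged row with
#' `NA` statistics rather than an error.
#'
#' @param variant Variant id (column of the genotype matrix).
#' @param exposure Exposure column name in `cohort` (binary 0/1 or
#'   continuous).
#' @param outcome Outcome label.
#' @param model Covariate preset (`"model1"`..`"model4"`).
#' @param cohort Cohort data frame (complete covariates; impute first).
#' @param genos A [genotype_matrix()] aligned with `cohort`.
#' @return One-row data frame with `beta_int`, `se`, `z`, `p_int`, the
#'   interaction HR with 95% CI, and a convergence flag.
#' @export
test_interaction <- function(variant, exposure, outcome = "dementia",
                             model = "model1", cohort, genos) {
  stopifnot(inherits(genos, "genotype_matrix"))
  cohort <- align_cohort(genos, cohort)
  if (!variant %in% genos$variants$id) stop("unknown variant: ", variant)
  test_interaction_core(genos$dosages[, variant], exposure, outcome, model,
                        cohort, variant_id = variant)
}

#' Subgroup hazard-ratio profile for one variant
#'
#' Estimates (i) the exposure hazard ratio within each hard-called
#' genotype group (dosages rounded to 0/1/2) and (ii) the per-allele
#' dosage hazard ratio within each exposure group, each adjusted for age,
#' sex and the top 10 principal components. Any subgroup with five or
#' fewer incident events (or no members) is flagged `excluded` and not
#' estimated.
#'
#' @inheritParams test_interaction
#' @param min_events Exclusion threshold: subgroups with this many events
#'   or fewer are flagged, not estimated (default 5).
#' @return List of two data frames: `hr_exposure_by_genotype` (rows
#'   genotype 0/1/2) and `hr_snp_by_exposure` (rows exposed/unexposed),
#'   each with `n`, `n_events`, `excluded`, and Wald columns.
#' @export
subgroup_hrs <- function(variant, exposure, outcome = "dementia",
                         cohort, genos, min_events = 5L) {
  stopifnot(inherits(genos, "genotype_matrix"))
  cohort <- align_cohort(genos, cohort)
  d <- genos$dosages[, variant]
  hard <- as.integer(round(d))
  ev_col <- paste0("event_", outcome)
  covars <- model_covariates("model1")
  wald_na <- data.frame(beta = NA_real_, se = NA_real_, z = NA_real_,
                        p = NA_real_, hr = NA_real_, hr_lo = NA_real_,
                        hr_hi = NA_real_)
  one_group <- function(keep, term_col) {
    sub <- cohort[keep, , drop = FALSE]
    n_ev <- sum(sub[[ev_col]], na.rm = TRUE)
    excluded <- sum(keep, na.rm = TRUE) == 0L || n_ev <= min_events
    if (!excluded) {
      sub$.x <- term_col[keep]
      w <- tryCatch(wald_test(fit_cox(sub, c(covars, ".x"), outcome), ".x"),
                    error = function(e) cbind(term = ".x", wald_na))
      w$term <- NULL
    } else {
      w <- wald_na
    }
    cbind(data.frame(n = sum(keep, na.rm = TRUE), n_events = n_ev,
                     excluded = excluded), w)
  }
  e <- cohort[[exposure]]
  by_geno <- do.call(rbind, lapply(0:2, function(g) {
    cbind(data.frame(genotype = g),
          one_group(!is.na(hard) & hard == g, e))
  }))
  d_imp <- d; d_imp[is.na(d_imp)] <- mean(d_imp, na.rm = TRUE)
  by_exp <- do.call(rbind, lapply(c(1, 0), function(x) {
    cbind(data.frame(exposure_level = x),
          one_group(!is.na(e) & e == x, d_imp))
  }))
  list(hr_exposure_by_genotype = by_geno, hr_snp_by_exposure = by_exp)
}

#' APOE epsilon-4 positive-control interaction test
#'
#' Runs the interaction model with the epsilon-4 dosage (0/1/2) in place
#' of a variant dosage; samples with excluded (ambiguous or missing)
#' dosage are dropped from the fit.
#'
#' @param cohort Cohort data frame containing an `apoe_e4_dosage` column
#'   (integer 0/1/2 with `NA` for excluded samples).
#' @inheritParams test_interaction
#' @return One-row interaction result data frame; `n_used` records the
#'   sample count after exclusion.
#' @export
apoe_positive_control <- function(cohort, exposure = "fos",
                                  outcome = "dementia", model = "model1") {
  if (!"apoe_e4_dosage" %in% names(cohort)) {
    stop("cohort has no apoe_e4_dosage column; derive it with apoe_e4_dosage()")
  }
  keep <- !is.na(cohort$apoe_e4_dosage)
  sub <- cohort[keep, , drop = FALSE]
  res <- test_interaction_core(sub$apoe_e4_dosage, exposure, outcome, model,
                               sub, variant_id = "APOE_e4")
  res$n_used <- sum(keep)
  res
}

#' Replication of primary interaction loci with an alternative exposure
#'
#' A locus replicates when at least one member SNP attains interaction
#' p < 0.05 with the alternative exposure *and* the interaction
#' coefficient has the same sign as that SNP's primary result. Both
#' components are reported so alternative rules can be recomputed.
#'
#' @param primary Data frame of primary interaction results (one row per
#'   tested SNP: `variant_id`, `locus`, `beta_int`).
#' @param alt_exposure Alternative exposure column in `cohort`.
#' @inheritParams test_interaction
#' @param p_threshold Nominal replication threshold (default 0.05).
#' @return Data frame per locus: `locus`, `replicated`, `best_p`,
#'   `sign_concordant`.
#' @export
replicate_screen <- function(primary, alt_exposure, outcome = "dementia",
                             model = "model1", cohort, genos,
                             p_threshold = 0.05) {
  stopifnot(all(c("variant_id", "locus", "beta_int") %in% names(primary)))
  out <- lapply(split(primary, primary$locus), function(loc) {
    alt <- do.call(rbind, lapply(seq_len(nrow(loc)), function(i) {
      test_interaction(loc$variant_id[i], alt_exposure, outcome, model,
                       cohort, genos)
    }))
    ok <- !is.na(alt$p_int)
    concord <- ok & sign(alt$beta_int) == sign(loc$beta_int)
    rep_hit <- concord & alt$p_int < p_threshold
    data.frame(locus = loc$locus[1],
               replicated = any(rep_hit),
               best_p = if (any(ok)) min(alt$p_int[ok]) else NA_real_,
               sign_concordant = any(concord),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-model consistency of interaction results
#'
#' Pairwise Pearson correlations (with test p-values) of the interaction
#' coefficients and of -log10 interaction p-values across adjustment
#' models fitted on the same variants.
#'
#' @param results_by_model Named list of interaction result tables (one
#'   per model), each with `variant_id`, `beta_int`, `p_int`.
#' @return Data frame per model pair: `model_a`, `model_b`, `n`,
#'   `r_beta`, `p_r_beta`, `r_logp`, `p_r_logp`.
#' @export
compare_models <- function(results_by_model) {
  stopifnot(length(results_by_model) >= 2L)
  ids <- lapply(results_by_model, `[[`, "variant_id")
  shared <- Reduce(intersect, ids)
  if (length(shared) < 3L) stop("fewer than 3 shared variants across models")
  nm <- names(results_by_model)
  pairs <- utils::combn(length(results_by_model), 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- results_by_model[[pairs[1, k]]]
    b <- results_by_model[[pairs[2, k]]]
    a <- a[match(shared, a$variant_id), ]
    b <- b[match(shared, b$variant_id), ]
    ok <- !is.na(a$p_int) & !is.na(b$p_int)
    if (sum(ok) < 3L) stop("fewer than 3 jointly converged variants")
    tb <- stats::cor.test(a$beta_int[ok], b$beta_int[ok])
    tp <- stats::cor.test(-log10(a$p_int[ok]), -log10(b$p_int[ok]))
    data.frame(model_a = nm[pairs[1, k]], model_b = nm[pairs[2, k]],
               n = sum(ok),
               r_beta = unname(tb$estimate), p_r_beta = tb$p.value,
               r_logp = unname(tp$estimate), p_r_logp = tp$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Exact binomial test of subgroup discovery preference
#'
#' Two-sided exact binomial test of `k` loci discovered only in one
#' exposure subgroup out of `n` single-subgroup loci, against equal
#' probability 0.5: the p-value sums the probabilities of all outcomes no
#' more probable than the observed one (equivalently, twice the one-sided
#' tail at p0 = 0.5).
#'
#' @param k_user_only Count of loci suggestive only in the exposed
#'   subgroup.
#' @param n_single_subgroup Count of loci suggestive in exactly one
#'   subgroup.
#' @return Two-sided exact p-value.
#' @export
subgroup_preference_test <- function(k_user_only, n_single_subgroup) {
  stopifnot(k_user_only >= 0, n_single_subgroup >= k_user_only,
            n_single_subgroup >= 1)
  stats::binom.test(k_user_only, n_single_subgroup, p = 0.5)$p.value
}

#' Run the full two-step interaction screen
#'
#' Orchestrates: overall and exposure-stratified GWAS per outcome,
#' candidate selection (suggestive p, common MAF), clumping of suggestive
#' signals, span merging and extension into independent candidate loci,
#' a locus-level Bonferroni threshold pooled across outcomes and
#' discovery sources, interaction tests for every candidate under the
#' configured models, subgroup hazard-ratio profiles and optional
#' nearest-gene annotation for significant hits, and cross-model
#' comparison when several models are run. QC should be applied to
#' `genos` beforehand (see [variant_qc()]).
#'
#' @param genos A QC'd [genotype_matrix()].
#' @param cohort Aligned cohort data frame with complete covariates.
#' @param cfg A [screen_config()].
#' @param exposure Primary binary exposure column (default `"fos"`).
#' @param outcomes Outcome labels to screen.
#' @param genes Optional gene annotation for nearest-gene lookup.
#' @param out_dir Optional directory; when given, writes
#'   `interactions.tsv`, `loci.tsv`, per-scan summary statistics and
#'   `manifest.json` (config + locus counts; no timestamps, so reruns
#'   are byte-identical).
#' @return List: `gwas` (per outcome/source tables), `candidates`,
#'   `loci` (extended merged intervals), `n_loci`, `n_loci_per_outcome`,
#'   `threshold`, `interactions` (all models), `significant`,
#'   `subgroup_profiles`, `model_comparison`.
#' @export
run_screen <- function(genos, cohort, cfg = screen_config(),
                       exposure = "fos", outcomes = "dementia",
                       genes = NULL, out_dir = NULL) {
  stopifnot(inherits(cfg, "screen_config"))
  cohort <- align_cohort(genos, cohort)
  scans <- list(); cands <- list(); loci_by_outcome <- list()
  for (oc in outcomes) {
    overall <- run_gwas(genos, cohort, oc, "model1", NULL, cfg$spa_switch_z)
    users <- run_gwas(genos, cohort, oc, "model1",
                      stats::setNames(1, exposure), cfg$spa_switch_z)
    nonusers <- run_gwas(genos, cohort, oc, "model1",
                         stats::setNames(0, exposure), cfg$spa_switch_z)
    scans[[oc]] <- list(overall = overall, users = users, nonusers = nonusers)
    cand <- select_candidates(overall, users, nonusers, cfg)
    cand$outcome <- rep(oc, nrow(cand))
    cands[[oc]] <- cand
    # candidate loci: clump suggestive signals per discovery source, pool,
    # merge spans, extend
    clumps <- c(
      clump(overall, genos, cfg$candidate_p, cfg$clump_r2, cfg$window_bp),
      clump(users, genos, cfg$candidate_p, cfg$clump_r2, cfg$window_bp),
      clump(nonusers, genos, cfg$candidate_p, cfg$clump_r2, cfg$window_bp))
    merged <- merge_clumps(clumps, cfg$merge_gap_bp, source = oc)
    loci_by_outcome[[oc]] <- extend_loci(merged, cfg$pad_bp)
  }
  candidates <- do.call(rbind, cands)
  pooled <- do.call(rbind, lapply(loci_by_outcome, function(x) {
    x[, c("chrom", "start", "end", "min_p", "index_id", "index_pos")]
  }))
  n_per_outcome <- vapply(loci_by_outcome, nrow, 0L)
  # pooled denominator: merge extended intervals across outcomes once more
  pooled_loci <- if (nrow(pooled)) extend_loci(pooled, pad_bp = 0L) else pooled
  n_loci <- nrow(pooled_loci)
  threshold <- if (n_loci >= 1) bonferroni_threshold(n_loci, cfg$bonferroni_alpha) else NA_real_

  interactions <- NULL
  signif_tab <- NULL
  profiles <- list()
  model_cmp <- NULL
  if (!is.null(candidates) && nrow(candidates)) {
    rows <- list()
    for (mdl in cfg$models) {
      for (i in seq_len(nrow(candidates))) {
        r <- test_interaction(candidates$id[i], exposure,
                              candidates$outcome[i], mdl, cohort, genos)
        r$discovery_source <- candidates$discovery_source[i]
        rows[[length(rows) + 1L]] <- r
      }
    }
    interactions <- do.call(rbind, rows)
    interactions$significant <- !is.na(interactions$p_int) &
      interactions$p_int < threshold
    primary_model <- cfg$models[1]
    prim <- interactions[interactions$model == primary_model, , drop = FALSE]
    signif_tab <- prim[prim$significant, , drop = FALSE]
    if (nrow(signif_tab)) {
      if (!is.null(genes)) {
        ng <- do.call(rbind, lapply(seq_len(nrow(signif_tab)), function(i) {
          v <- genos$variants[genos$variants$id == signif_tab$variant_id[i], ]
          nearest_gene(v$chrom, v$pos, genes)
        }))
        signif_tab$closest_gene <- ng$symbol
        signif_tab$gene_distance <- ng$distance
      }
      profiles <- lapply(seq_len(nrow(signif_tab)), function(i) {
        subgroup_hrs(signif_tab$variant_id[i], exposure,
                     signif_tab$outcome[i], cohort, genos)
      })
      names(profiles) <- paste(signif_tab$variant_id, signif_tab$outcome,
                               sep = ":")
    }
    if (length(cfg$models) >= 2L) {
      by_model <- split(interactions, interactions$model)
      model_cmp <- tryCatch(compare_models(by_model), error = function(e) NULL)
    }
  }
  bundle <- list(gwas = scans, candidates = candidates,
                 loci = pooled_loci, loci_per_outcome = loci_by_outcome,
                 n_loci = n_loci, n_loci_per_outcome = n_per_outcome,
                 threshold = threshold, interactions = interactions,
                 significant = signif_tab, subgroup_profiles = profiles,
                 model_comparison = model_cmp, config = cfg)
  if (!is.null(out_dir)) write_screen_bundle(bundle, out_dir)
  bundle
}

# serialize the report bundle; deterministic (no timestamps)
write_screen_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (oc in names(bundle$gwas)) {
    for (src in names(bundle$gwas[[oc]])) {
      write_summary_stats(bundle$gwas[[oc]][[src]],
                          file.path(out_dir, sprintf("gwas_%s_%s.tsv", oc, src)))
    }
  }
  if (!is.null(bundle$interactions)) {
    data.table::fwrite(bundle$interactions,
                       file.path(out_dir, "interactions.tsv"),
                       sep = "\t", na = "NA", quote = FALSE)
  }
  loci_out <- bundle$loci
  if (!is.null(loci_out) && nrow(loci_out)) {
    data.table::fwrite(loci_out, file.path(out_dir, "loci.tsv"),
                       sep = "\t", na = "NA", quote = FALSE)
  }
  manifest <- list(
    package = "survgxe",
    version = as.character(utils::packageVersion("survgxe")),
    config = unclass(bundle$config),
    n_loci = bundle$n_loci,
    n_loci_per_outcome = as.list(bundle$n_loci_per_outcome),
    threshold = bundle$threshold,
    n_candidates = if (is.null(bundle$candidates)) 0L else nrow(bundle$candidates),
    n_significant = if (is.null(bundle$significant)) 0L else nrow(bundle$significant))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
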