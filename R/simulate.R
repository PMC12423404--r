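#' Specify a synthetic biobank-cohort simulation
#'
#' Collects every parameter of the genotype and cohort generators in one
#' validated object. Defaults emulate the statistical structure of a large
#' middle-aged prospective cohort: entry ages 40-69 (mean 56.81, SD 8.01),
#' 31.7% prevalence of the binary supplement exposure, a low constant
#' baseline hazard, administrative censoring at 13.8 years (so median
#' follow-up is about 13.8 years at low event rates), and genotypes in
#' Hardy-Weinberg proportions with block-autoregressive LD.
#'
#' @param n_samples,n_variants Cohort and panel sizes.
#' @param maf_range Range (0, 0.5] from which per-variant alternate allele
#'   frequencies are drawn uniformly.
#' @param ld_block_size Variants per LD block; a trailing short block is
#'   allowed.
#' @param ld_rho First-order autoregressive correlation of the latent
#'   Gaussians within a block, in [0, 1).
#' @param exposure_prevalence Probability of the binary exposure.
#' @param age_mean,age_sd,entry_age_range Entry-age truncated normal, years.
#' @param baseline_hazard_rate Constant baseline hazard, events per
#'   person-year.
#' @param admin_censor_years Administrative censoring time, years.
#' @param causal_effects Data frame with columns `variant` (1-based index),
#'   `beta_main` and `beta_gxe` (log hazard ratios), or `NULL`.
#' @param exposure_log_hr Log hazard ratio of the exposure itself.
#' @param covariate_log_hrs Named numeric vector of log hazard ratios for
#'   numeric covariates (age is centred at `age_mean` before entering the
#'   hazard).
#' @param missing_genotype_rate Completely-at-random genotype missingness.
#' @param exposure_confounded If `TRUE`, exposure probability depends on
#'   age and sex (logistic model) instead of being marginal Bernoulli.
#' @param subtype_probs Probabilities that an all-cause event is classified
#'   as the Alzheimer's or vascular subtype.
#' @param seed Single integer seed; all generator streams derive from it.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_samples = 5000L, n_variants = 1000L,
                            maf_range = c(0.01, 0.5), ld_block_size = 50L,
                            ld_rho = 0, exposure_prevalence = 0.317,
                            age_mean = 56.81, age_sd = 8.01,
                            entry_age_range = c(40, 69),
                            baseline_hazard_rate = 0.0015,
                            admin_censor_years = 13.8,
                            causal_effects = NULL,
                            exposure_log_hr = log(0.92),
                            covariate_log_hrs = c(age = 0.1, sex = 0.15),
                            missing_genotype_rate = 0,
                            exposure_confounded = FALSE,
                            subtype_probs = c(ad = 0.55, vad = 0.25),
                            seed = 1L) {
  stopifnot(n_samples >= 1, n_variants >= 1, ld_block_size >= 1)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  if (exposure_prevalence <= 0 || exposure_prevalence >= 1) {
    stop("exposure_prevalence must be in (0, 1)")
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (missing_genotype_rate < 0 || missing_genotype_rate >= 1) {
    stop("missing_genotype_rate must be in [0, 1)")
  }
  if (baseline_hazard_rate <= 0 || admin_censor_years <= 0) {
    stop("baseline_hazard_rate and admin_censor_years must be positive")
  }
  if (!is.null(causal_effects)) {
    causal_effects <- as.data.frame(causal_effects)
    stopifnot(all(c("variant", "beta_main", "beta_gxe") %in% names(causal_effects)))
    if (any(causal_effects$variant < 1 | causal_effects$variant > n_variants)) {
      stop("causal_effects variant indices must be in 1..n_variants")
    }
  }
  if (sum(subtype_probs) > 1) stop("subtype_probs must sum to at most 1")
  structure(list(
    n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
    maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
    ld_rho = ld_rho, exposure_prevalence = exposure_prevalence,
    age_mean = age_mean, age_sd = age_sd, entry_age_range = entry_age_range,
    baseline_hazard_rate = baseline_hazard_rate,
    admin_censor_years = admin_censor_years,
    causal_effects = causal_effects, exposure_log_hr = exposure_log_hr,
    covariate_log_hrs = covariate_log_hrs,
    missing_genotype_rate = missing_genotype_rate,
    exposure_confounded = exposure_confounded,
    subtype_probs = subtype_probs, seed = as.integer(seed)
  ), class = "simulation_spec")
}

#' Construct a genotype matrix object
#'
#' @param dosages Numeric samples x variants matrix, values in [0, 2],
#'   `NA` for missing.
#' @param variants Data frame with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `maf`, `info`, `call_rate`, `hwe_p`, sorted by
#'   (chrom, pos); positions 1-based.
#' @param sample_ids Character vector, one per row of `dosages`.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, sample_ids) {
  stopifnot(is.matrix(dosages), nrow(variants) == ncol(dosages),
            length(sample_ids) == nrow(dosages))
  if (length(dosages) && !all(is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  }
  ord <- order(variants$chrom, variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    variants <- variants[ord, , drop = FALSE]
    dosages <- dosages[, ord, drop = FALSE]
  }
  colnames(dosages) <- variants$id
  rownames(dosages) <- sample_ids
  structure(list(dosages = dosages, variants = variants,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants, %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Simulate genotype dosages with block LD in Hardy-Weinberg proportions
#'
#' Per-variant alternate allele frequencies are drawn uniformly from
#' `maf_range`. Within each block of `ld_block_size` variants, genotypes
#' derive from latent standard Gaussians with first-order autoregressive
#' correlation `ld_rho`, thresholded into the three genotype classes at the
#' Hardy-Weinberg proportions \eqn{(1-p)^2, 2p(1-p), p^2}. Missingness is
#' applied completely at random. Deterministic given `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return A [genotype_matrix()] with metadata (`maf` is the drawn target
#'   frequency; `call_rate` and `hwe_p` are computed from the realized
#'   data; `info` is 1 for simulated genotypes).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples; m <- spec$n_variants
  p_alt <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
  G <- matrix(NA_real_, n, m)
  block_starts <- seq(1L, m, by = spec$ld_block_size)
  for (bs in block_starts) {
    be <- min(bs + spec$ld_block_size - 1L, m)
    k <- be - bs + 1L
    Z <- matrix(stats::rnorm(n * k), n, k)
    if (spec$ld_rho > 0 && k > 1L) {
      for (j in 2:k) {
        Z[, j] <- spec$ld_rho * Z[, j - 1L] + sqrt(1 - spec$ld_rho^2) * Z[, j]
      }
    }
    U <- stats::pnorm(Z)
    for (j in seq_len(k)) {
      p <- p_alt[bs + j - 1L]
      q0 <- (1 - p)^2
      G[, bs + j - 1L] <- (U[, j] > q0) + (U[, j] > q0 + 2 * p * (1 - p))
    }
  }
  if (spec$missing_genotype_rate > 0) {
    G[stats::runif(n * m) < spec$missing_genotype_rate] <- NA_real_
  }
  ids <- sprintf("var%0*d", max(5L, nchar(m)), seq_len(m))
  variants <- data.frame(
    chrom = "1",
    pos = 1L + (seq_len(m) - 1L) * 10000L,
    id = ids, ref = "A", alt = "G",
    maf = p_alt, info = 1,
    call_rate = colMeans(!is.na(G)),
    hwe_p = hwe_from_dosages(G),
    stringsAsFactors = FALSE
  )
  genotype_matrix(G, variants, sprintf("S%06d", seq_len(n)))
}

# HWE exact p per column of a dosage matrix, on hard-called genotypes
hwe_from_dosages <- function(G) {
  apply(G, 2, function(g) {
    g <- round(g[!is.na(g)])
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
}

# truncated normal via inverse-CDF on the truncated uniform range
rtruncnorm_ <- function(n, mean, sd, lo, hi) {
  a <- stats::pnorm(lo, mean, sd); b <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, a, b), mean, sd)
}

#' Simulate survival outcomes, exposure and covariates for a genotype panel
#'
#' Entry age is truncated normal within `entry_age_range`; sex is
#' Bernoulli(0.5); ten synthetic principal components are standard normal;
#' the binary exposure is Bernoulli(`exposure_prevalence`) (optionally
#' age/sex-dependent). Event times follow an exponential proportional
#' hazards model with linear predictor
#' covariate effects + exposure effect + per-variant main effects +
#' dosage-by-exposure interaction effects, administratively censored at
#' `admin_censor_years`. All-cause events are probabilistically classified
#' into Alzheimer's and vascular subtypes, giving cause-specific event
#' indicators that share one follow-up time. Lifestyle, diet and
#' medical-history covariates for the richer adjustment models are drawn
#' from fixed plausible marginals (see the methods vignette).
#'
#' @param spec A [simulation_spec()].
#' @param genos The [genotype_matrix()] generated from the same spec.
#' @return Data frame (one row per sample): `sample_id`, `time_years`,
#'   `event_dementia`, `event_ad`, `event_vad`, `fos`, `oily_fish`,
#'   `omega3`, `age`, `sex`, `pc1`..`pc10`, and the model-2/3/4
#'   covariates.
#' @export
simulate_cohort <- function(spec, genos) {
  stopifnot(inherits(spec, "simulation_spec"), inherits(genos, "genotype_matrix"))
  n <- spec$n_samples
  if (nrow(genos$dosages) != n) {
    stop("genotype matrix has ", nrow(genos$dosages),
         " samples but spec expects ", n, " (misaligned inputs)")
  }
  set.seed(spec$seed + 1L)
  age <- rtruncnorm_(n, spec$age_mean, spec$age_sd,
                     spec$entry_age_range[1], spec$entry_age_range[2])
  sex <- stats::rbinom(n, 1L, 0.5)
  pcs <- matrix(stats::rnorm(n * 10L), n, 10L,
                dimnames = list(NULL, paste0("pc", 1:10)))
  if (spec$exposure_confounded) {
    lp_e <- stats::qlogis(spec$exposure_prevalence) +
      0.04 * (age - spec$age_mean) - 0.35 * (sex - 0.5)
    fos <- stats::rbinom(n, 1L, stats::plogis(lp_e))
  } else {
    fos <- stats::rbinom(n, 1L, spec$exposure_prevalence)
  }
  oily_fish <- stats::rbinom(n, 1L, stats::plogis(stats::qlogis(0.5) + 0.4 * fos))
  omega3 <- stats::rnorm(n, 0.44 + 0.08 * fos, 0.12)

  lvl3 <- function(p) factor(sample(c("low", "medium", "high"), n, TRUE, p),
                             levels = c("low", "medium", "high"))
  covs <- data.frame(
    education = stats::rbinom(n, 1L, 0.33),
    tdi = stats::rnorm(n, -1.3, 3.0),
    bmi = stats::rnorm(n, 27.4, 4.8),
    smoking = factor(sample(c("never", "previous", "current"), n, TRUE,
                            c(0.55, 0.35, 0.10)),
                     levels = c("never", "previous", "current")),
    alcohol = factor(sample(c("non", "moderate", "heavy"), n, TRUE,
                            c(0.08, 0.72, 0.20)),
                     levels = c("non", "moderate", "heavy")),
    physical_activity = stats::rlnorm(n, 3.2, 0.8),
    diet_oily_fish = lvl3(c(0.35, 0.45, 0.20)),
    diet_fruit = lvl3(c(0.30, 0.50, 0.20)),
    diet_vegetable = lvl3(c(0.25, 0.55, 0.20)),
    diet_processed_meat = factor(sample(c("low", "high"), n, TRUE, c(0.6, 0.4)),
                                 levels = c("low", "high")),
    diet_red_meat = factor(sample(c("low", "high"), n, TRUE, c(0.55, 0.45)),
                           levels = c("low", "high")),
    suppl_vitamin = stats::rbinom(n, 1L, 0.25),
    suppl_mineral = stats::rbinom(n, 1L, 0.15),
    suppl_glucosamine = stats::rbinom(n, 1L, 0.18),
    hx_hypertension = stats::rbinom(n, 1L, 0.27),
    hx_cvd = stats::rbinom(n, 1L, 0.06),
    hx_high_cholesterol = stats::rbinom(n, 1L, 0.13),
    hx_diabetes = stats::rbinom(n, 1L, 0.05),
    hx_depression = stats::rbinom(n, 1L, 0.06)
  )

  lp <- rep(0, n)
  clh <- spec$covariate_log_hrs
  if (length(clh)) {
    base_cols <- data.frame(age = age - spec$age_mean, sex = sex,
                            fos = fos, oily_fish = oily_fish,
                            omega3 = omega3, pcs, covs[sapply(covs, is.numeric)])
    for (nm in names(clh)) {
      if (!nm %in% names(base_cols)) stop("unknown covariate in covariate_log_hrs: ", nm)
      lp <- lp + clh[[nm]] * base_cols[[nm]]
    }
  }
  lp <- lp + spec$exposure_log_hr * fos
  if (!is.null(spec$causal_effects)) {
    for (r in seq_len(nrow(spec$causal_effects))) {
      j <- spec$causal_effects$variant[r]
      d <- genos$dosages[, j]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      lp <- lp + spec$causal_effects$beta_main[r] * d +
        spec$causal_effects$beta_gxe[r] * d * fos
    }
  }
  rate <- spec$baseline_hazard_rate * exp(lp)
  t_event <- stats::rexp(n) / rate
  event <- as.integer(t_event <= spec$admin_censor_years)
  time <- pmin(t_event, spec$admin_censor_years)
  # classify all-cause events into subtypes (cause-specific indicators)
  sub <- rep("none", n)
  idx <- which(event == 1L)
  if (length(idx)) {
    sub[idx] <- sample(c("ad", "vad", "other"), length(idx), TRUE,
                       c(spec$subtype_probs["ad"], spec$subtype_probs["vad"],
                         1 - sum(spec$subtype_probs)))
  }
  data.frame(
    sample_id = genos$sample_ids,
    time_years = time,
    event_dementia = event,
    event_ad = as.integer(sub == "ad"),
    event_vad = as.integer(sub == "vad"),
    fos = fos, oily_fish = oily_fish, omega3 = omega3,
    age = age, sex = sex, pcs, covs,
    stringsAsFactors = FALSE
  )
}
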