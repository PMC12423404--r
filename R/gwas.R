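#' Hardy-Weinberg equilibrium exact test
#'
#' Exact conditional test: given the allele counts, the p-value is the sum
#' of probabilities of all heterozygote counts whose probability under the
#' Hardy-Weinberg (hypergeometric-type) distribution is at most that of the
#' observed count. Probabilities are computed by the stable mid-out
#' recurrence. Monomorphic sites return 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total > 0).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0L) stop("total genotype count must be positive")
  n_rare <- 2L * min(n_AA, n_aa) + n_Aa       # rare allele count
  if (n_rare == 0L || n_rare == 2L * n) return(1)
  # possible het counts share the parity of the rare allele count
  h_min <- if (n_rare %% 2L == 0L) 0L else 1L
  h_max <- min(n_rare, 2L * n - n_rare)
  hs <- seq.int(h_min, h_max, by = 2L)
  probs <- numeric(length(hs))
  # start at the mode-ish expected het count, recur both directions
  h_mid <- round(n_rare * (2 * n - n_rare) / (2 * n))
  if ((h_mid %% 2L) != (n_rare %% 2L)) h_mid <- h_mid + 1L
  h_mid <- min(max(h_mid, h_min), h_max)
  i_mid <- match(h_mid, hs)
  probs[i_mid] <- 1
  # P(h-2)/P(h) = h(h-1) / ((hom_rare+1)(hom_common+1) * 4)
  if (i_mid > 1L) {
    for (i in seq(i_mid - 1L, 1L)) {
      h <- hs[i + 1L]
      hom_r <- (n_rare - h) / 2
      hom_c <- n - h - hom_r
      probs[i] <- probs[i + 1L] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  if (i_mid < length(hs)) {
    for (i in seq(i_mid + 1L, length(hs))) {
      h <- hs[i - 1L]
      hom_r <- (n_rare - h) / 2
      hom_c <- n - h - hom_r
      probs[i] <- probs[i - 1L] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

#' Variant and sample quality control
#'
#' Drops variants failing, in this fixed order (each removal attributed to
#' the first failing filter): imputation info score, biallelic status,
#' minor allele frequency, per-variant call rate, and Hardy-Weinberg exact
#' test on hard-called genotypes (dosages rounded to the nearest genotype;
#' exact .5 rounds ties-to-even). Then drops samples whose call rate over
#' the surviving variants is below threshold.
#'
#' @param genos A [genotype_matrix()].
#' @param thresholds List with elements `info` (keep >= 0.3), `maf`
#'   (keep >= 0.001), `variant_call_rate` (keep >= 0.95), `hwe_p`
#'   (keep >= 1e-8), `sample_call_rate` (keep >= 0.98).
#' @return List: `genos` (filtered) and `report` (class `qc_report`).
#' @export
variant_qc <- function(genos,
                       thresholds = list(info = 0.3, maf = 0.001,
                                         variant_call_rate = 0.95,
                                         hwe_p = 1e-8,
                                         sample_call_rate = 0.98)) {
  stopifnot(inherits(genos, "genotype_matrix"))
  G <- genos$dosages; V <- genos$variants
  m <- ncol(G)
  af <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  call_rate <- colMeans(!is.na(G))
  hwe_p <- hwe_from_dosages(G)
  biallelic <- !grepl(",", V$alt) & nchar(V$ref) == 1L & nchar(V$alt) == 1L

  fail_info <- V$info < thresholds$info
  fail_bi <- !biallelic
  fail_maf <- maf < thresholds$maf | is.nan(maf)
  fail_call <- call_rate < thresholds$variant_call_rate
  fail_hwe <- hwe_p < thresholds$hwe_p

  reason <- rep(NA_character_, m)
  reason[fail_hwe] <- "hwe"
  reason[fail_call] <- "missingness"
  reason[fail_maf] <- "maf"
  reason[fail_bi] <- "non_biallelic"
  reason[fail_info] <- "info"            # first filter in order wins
  keep_v <- is.na(reason)
  if (!any(keep_v)) stop("all variants removed by QC")

  G2 <- G[, keep_v, drop = FALSE]
  sample_cr <- rowMeans(!is.na(G2))
  keep_s <- sample_cr >= thresholds$sample_call_rate

  out <- genotype_matrix(G2[keep_s, , drop = FALSE],
                         V[keep_v, , drop = FALSE],
                         genos$sample_ids[keep_s])
  report <- structure(list(
    n_variants_in = m, n_variants_out = sum(keep_v),
    variant_removals = c(info = sum(reason == "info", na.rm = TRUE),
                         non_biallelic = sum(reason == "non_biallelic", na.rm = TRUE),
                         maf = sum(reason == "maf", na.rm = TRUE),
                         missingness = sum(reason == "missingness", na.rm = TRUE),
                         hwe = sum(reason == "hwe", na.rm = TRUE)),
    n_samples_in = nrow(G), n_samples_out = sum(keep_s),
    sample_removals = c(call_rate = sum(!keep_s)),
    thresholds = thresholds
  ), class = "qc_report")
  list(genos = out, report = report)
}

#' @method print qc_report
#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("variant QC: %d -> %d variants\n", x$n_variants_in, x$n_variants_out))
  print(x$variant_removals)
  cat(sprintf("sample QC: %d -> %d samples (call rate)\n",
              x$n_samples_in, x$n_samples_out))
  invisible(x)
}

#' Prune related samples
#'
#' Removes, first, samples appearing in more than `max_pairs` pairs closer
#' than the third-degree kinship cutoff (excessive relatives); then walks
#' the remaining above-cutoff pairs in deterministic (sorted) order and,
#' where both members are still present, removes one member uniformly at
#' random under the supplied seed.
#'
#' @param pairs Data frame with columns `id1`, `id2`, `kinship`
#'   (kinship >= 0).
#' @param samples Character vector of all sample ids.
#' @param seed Integer seed for the random member choice.
#' @param kinship_cutoff Third-degree kinship cutoff (default 0.0442).
#' @param max_pairs Excessive-relative threshold (default 10).
#' @return Character vector of kept sample ids (original order).
#' @export
prune_relatives <- function(pairs, samples, seed = 1L,
                            kinship_cutoff = 0.0442, max_pairs = 10L) {
  if (nrow(pairs) == 0L) return(samples)
  stopifnot(all(c("id1", "id2", "kinship") %in% names(pairs)),
            all(pairs$kinship >= 0))
  bad <- setdiff(c(pairs$id1, pairs$id2), samples)
  if (length(bad)) stop("pair ids not in sample list: ", paste(bad, collapse = ", "))
  close_p <- pairs[pairs$kinship > kinship_cutoff, , drop = FALSE]
  if (nrow(close_p) == 0L) return(samples)
  counts <- table(c(close_p$id1, close_p$id2))
  removed <- names(counts)[counts > max_pairs]
  close_p <- close_p[order(close_p$id1, close_p$id2), , drop = FALSE]
  set.seed(seed)
  for (i in seq_len(nrow(close_p))) {
    a <- close_p$id1[i]; b <- close_p$id2[i]
    if (a %in% removed || b %in% removed) next
    removed <- c(removed, if (stats::runif(1) < 0.5) a else b)
  }
  setdiff(samples, removed)
}

# Match a cohort table to the rows of a genotype matrix by sample_id
# (after sample QC the genotype matrix may hold a subset of the cohort).
align_cohort <- function(genos, cohort) {
  if (nrow(cohort) == nrow(genos$dosages)) return(cohort)
  if (!"sample_id" %in% names(cohort)) {
    stop("cohort and genotypes misaligned and cohort has no sample_id column")
  }
  idx <- match(genos$sample_ids, cohort$sample_id)
  if (anyNA(idx)) stop("cohort is missing samples present in the genotype matrix")
  cohort[idx, , drop = FALSE]
}

# Saddlepoint machinery -------------------------------------------------

# CGF of S = sum_i G_i * r_i with G_i iid HWE(p) genotypes and fixed
# covariate-projected residuals r (which sum to zero, so K'(0) = 0).
spa_cgf <- function(t, r, p) {
  q0 <- (1 - p)^2; q1 <- 2 * p * (1 - p); q2 <- p^2
  e1 <- exp(t * r); e2 <- e1 * e1
  den <- q0 + q1 * e1 + q2 * e2
  list(
    k = sum(log(den)) - t * 2 * p * sum(r),
    k1 = sum(r * (q1 * e1 + 2 * q2 * e2) / den) - 2 * p * sum(r),
    k2 = {
      m1 <- (q1 * e1 + 2 * q2 * e2) / den
      m2 <- (q1 * e1 + 4 * q2 * e2) / den
      sum(r^2 * (m2 - m1^2))
    }
  )
}

# Upper tail P(S >= s), s > 0, by Lugannani-Rice at the saddlepoint of
# K'(zeta) = s. Safeguarded Newton with bracket expansion. NULL on failure.
spa_tail <- function(s, r, p) {
  # upper support bound of centred S: sum over i of max_g (g - 2p) r_i
  s_sup <- sum(pmax((0 - 2 * p) * r, (1 - 2 * p) * r, (2 - 2 * p) * r))
  if (s >= s_sup) return(NULL)
  lo <- 0; hi <- 1
  k1 <- spa_cgf(hi, r, p)$k1
  tries <- 0L
  while (k1 < s) {
    lo <- hi; hi <- hi * 2
    k1 <- spa_cgf(hi, r, p)$k1
    tries <- tries + 1L
    if (tries > 200L || !is.finite(k1)) return(NULL)
  }
  zeta <- min(hi, max(lo, s / max(spa_cgf(0, r, p)$k2, 1e-300)))
  for (it in 1:100) {
    cg <- spa_cgf(zeta, r, p)
    f <- cg$k1 - s
    if (abs(f) < 1e-9 * (1 + abs(s))) break
    if (f > 0) hi <- zeta else lo <- zeta
    step <- f / max(cg$k2, 1e-300)
    zeta_new <- zeta - step
    if (!is.finite(zeta_new) || zeta_new <= lo || zeta_new >= hi) {
      zeta_new <- (lo + hi) / 2
    }
    zeta <- zeta_new
    if (it == 100L) return(NULL)
  }
  cg <- spa_cgf(zeta, r, p)
  arg <- 2 * (zeta * s - cg$k)
  if (arg <= 0 || cg$k2 <= 0) return(NULL)
  w <- sqrt(arg)
  v <- zeta * sqrt(cg$k2)
  if (abs(w) < 1e-6) return(NULL)
  pt <- stats::pnorm(w, lower.tail = FALSE) + stats::dnorm(w) * (1 / v - 1 / w)
  if (!is.finite(pt) || pt < 0) return(NULL)
  pt
}

# Two-sided saddlepoint p-value for observed score s (any sign):
# P(S >= |s|) + P(S <= -|s|); the lower tail is the upper tail of -S,
# whose CGF is K(-t). NULL if either saddlepoint fails.
spa_pvalue <- function(s, r, p) {
  s_abs <- abs(s)
  up <- spa_tail(s_abs, r, p)
  lo <- spa_tail(s_abs, -r, p)  # -S = sum G_i * (-r_i)
  if (is.null(up) || is.null(lo)) return(NULL)
  min(1, up + lo)
}

#' Score test for one variant against a fitted null Cox model
#'
#' The dosage vector is mean-imputed for missing values and residualized on
#' the null-model covariates (plus intercept) by least-squares projection;
#' the score is \eqn{S = \sum_i \tilde g_i r_i} with \eqn{r} the null-model
#' martingale residuals. The variance is the exact permutation variance
#' \eqn{V = \sum_i (g_i-\bar g)^2 \sum_i \tilde r_i^2/(n-1)}, which makes
#' \eqn{z^2 = S^2/V} chi-squared calibrated under genotype permutation.
#' When \eqn{|z|} exceeds `spa_switch_z`, the tail probability is
#' recomputed by saddlepoint approximation (Lugannani-Rice) of the score's
#' cumulant generating function, treating residuals as fixed and genotypes
#' as Hardy-Weinberg distributed at the observed allele frequency.
#'
#' @param dosage Per-sample dosage vector (may contain `NA`).
#' @param null A `cox_fit` for the null model on the same samples.
#' @param covariates Design matrix used in the null fit (defaults to the
#'   matrix stored in the fit).
#' @param spa_switch_z Hybrid switch: saddlepoint is attempted only when
#'   `|z|` exceeds this (default 2, the convention in the saddlepoint GWAS
#'   literature).
#' @return One-row data frame: `af`, `n`, `score`, `variance`, `z`,
#'   `p_normal`, `p_spa`, `p` (the hybrid p-value), `method`
#'   (`"normal"`, `"spa"`, `"spa_failed_fallback"`, or
#'   `"non_testable"`).
#' @export
score_test <- function(dosage, null, covariates = null$X, spa_switch_z = 2) {
  stopifnot(inherits(null, "cox_fit"), length(dosage) == null$n)
  qrX <- qr(cbind(1, covariates))
  r_t <- qr.resid(qrX, null$martingale_residuals)
  score_test_core(dosage, r_t, spa_switch_z)
}

# core on precomputed projected residuals r_t
score_test_core <- function(dosage, r_t, spa_switch_z = 2) {
  g <- dosage
  na <- is.na(g)
  if (any(na)) g[na] <- mean(g, na.rm = TRUE)
  n <- length(g)
  af <- mean(g) / 2
  ssg <- sum((g - mean(g))^2)
  if (ssg == 0) {
    return(data.frame(af = af, n = n, score = 0, variance = 0, z = NA_real_,
                      p_normal = NA_real_, p_spa = NA_real_, p = NA_real_,
                      method = "non_testable", stringsAsFactors = FALSE))
  }
  S <- sum(g * r_t)
  V <- ssg * sum(r_t^2) / (n - 1)
  if (V <= 0) {
    # degenerate null (e.g. residuals all zero): no evidence either way
    return(data.frame(af = af, n = n, score = S, variance = V, z = 0,
                      p_normal = 1, p_spa = 1, p = 1,
                      method = "normal", stringsAsFactors = FALSE))
  }
  z <- S / sqrt(V)
  p_norm <- 2 * stats::pnorm(-abs(z))
  method <- "normal"
  p_spa <- p_norm
  if (abs(z) > spa_switch_z) {
    ps <- spa_pvalue(S, r_t, af)
    if (is.null(ps)) {
      method <- "spa_failed_fallback"
    } else {
      p_spa <- ps
      method <- "spa"
    }
  }
  data.frame(af = af, n = n, score = S, variance = V, z = z,
             p_normal = p_norm, p_spa = p_spa,
             p = if (method == "spa") p_spa else p_norm,
             method = method, stringsAsFactors = FALSE)
}

#' Run a time-to-event GWAS over all variants
#'
#' Fits one null Cox model per (outcome, subgroup) with the requested
#' covariate preset, then applies the score test (with saddlepoint hybrid)
#' to every variant. QC is assumed to have been applied already.
#'
#' @param genos A [genotype_matrix()].
#' @param cohort Cohort data frame aligned with `genos` rows.
#' @param outcome Outcome label (selects `event_<outcome>`).
#' @param covariates Covariate preset name (see [model_covariates()]) or a
#'   character vector of covariate columns.
#' @param subgroup `NULL` for the full cohort, or a one-element named
#'   vector such as `c(fos = 1)` restricting to an exposure stratum.
#' @param spa_switch_z Hybrid switch threshold passed to the score test.
#' @param block_size Variants per processing block.
#' @return Data frame: one row per variant with `chrom`, `pos`, `id`,
#'   `ref`, `alt`, `af`, `n`, `n_events`, `score`, `variance`, `z`,
#'   `p_normal`, `p_spa`, `p`, `method`.
#' @export
run_gwas <- function(genos, cohort, outcome = "dementia",
                     covariates = "model1", subgroup = NULL,
                     spa_switch_z = 2, block_size = 2000L) {
  stopifnot(inherits(genos, "genotype_matrix"))
  cohort <- align_cohort(genos, cohort)
  if (length(covariates) == 1L && covariates %in% paste0("model", 1:4)) {
    covariates <- model_covariates(covariates)
  }
  keep <- rep(TRUE, nrow(cohort))
  if (!is.null(subgroup)) {
    stopifnot(length(subgroup) == 1L, !is.null(names(subgroup)))
    keep <- cohort[[names(subgroup)]] == subgroup[[1]]
    keep[is.na(keep)] <- FALSE
  }
  sub_cohort <- cohort[keep, , drop = FALSE]
  ev_col <- paste0("event_", outcome)
  if (sum(sub_cohort[[ev_col]]) == 0L) {
    stop("subgroup has zero events for outcome ", outcome)
  }
  null <- fit_cox(sub_cohort, covariates, outcome)
  qrX <- qr(cbind(1, null$X))
  r_t <- qr.resid(qrX, null$martingale_residuals)
  G <- genos$dosages[keep, , drop = FALSE]
  m <- ncol(G)
  n <- nrow(G)
  ssr <- sum(r_t^2)
  res <- vector("list", ceiling(m / block_size))
  bi <- 0L
  for (bs in seq(1L, m, by = block_size)) {
    be <- min(bs + block_size - 1L, m)
    blk <- G[, bs:be, drop = FALSE]
    na_idx <- which(is.na(blk))
    if (length(na_idx)) {
      cm_na <- colMeans(blk, na.rm = TRUE)
      blk[na_idx] <- cm_na[((na_idx - 1L) %/% n) + 1L]
    }
    S <- drop(crossprod(blk, r_t))
    cmn <- colMeans(blk)
    ssg <- colSums(blk^2) - n * cmn^2
    ssg[ssg < 0] <- 0
    V <- ssg * ssr / (n - 1)
    z <- ifelse(V > 0, S / sqrt(V), NA_real_)
    p_norm <- 2 * stats::pnorm(-abs(z))
    p_spa <- p_norm
    method <- ifelse(ssg == 0, "non_testable",
                     ifelse(V > 0, "normal", "normal"))
    p_norm[V <= 0 & ssg > 0] <- 1   # degenerate null residuals
    p_spa[V <= 0 & ssg > 0] <- 1
    z[V <= 0 & ssg > 0] <- 0
    for (j in which(!is.na(z) & abs(z) > spa_switch_z)) {
      ps <- spa_pvalue(S[j], r_t, cmn[j] / 2)
      if (is.null(ps)) {
        method[j] <- "spa_failed_fallback"
      } else {
        p_spa[j] <- ps
        method[j] <- "spa"
      }
    }
    bi <- bi + 1L
    res[[bi]] <- data.frame(af = cmn / 2, n = n, score = S, variance = V,
                            z = z, p_normal = p_norm, p_spa = p_spa,
                            p = ifelse(method == "spa", p_spa, p_norm),
                            method = method, stringsAsFactors = FALSE)
  }
  out <- cbind(genos$variants[, c("chrom", "pos", "id", "ref", "alt")],
               do.call(rbind, res))
  out$n_events <- null$n_events
  rownames(out) <- NULL
  out[, c("chrom", "pos", "id", "ref", "alt", "af", "n", "n_events",
          "score", "variance", "z", "p_normal", "p_spa", "p", "method")]
}

#' Genomic inflation factor
#'
#' Median of the squared z statistics divided by the null median of a
#' one-degree chi-squared variate (0.4549...).
#'
#' @param results GWAS result data frame with a `z` column, or a numeric
#'   vector of z statistics. At least 100 tests required.
#' @return Lambda GC.
#' @export
genomic_inflation <- function(results) {
  z <- if (is.data.frame(results)) results$z else results
  z <- z[!is.na(z)]
  if (length(z) < 100L) stop("need at least 100 test statistics")
  stats::median(z^2) / stats::qchisq(0.5, df = 1)
}
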