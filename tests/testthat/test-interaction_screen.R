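fake_gwas_table <- function(ids, p, af = 0.3) {
  m <- length(ids)
  data.frame(chrom = "1", pos = seq_len(m) * 10000L, id = ids,
             ref = "A", alt = "G", af = rep(af, m)[seq_len(m)], n = 1000L,
             n_events = 100L, score = 0, variance = 1, z = 0,
             p_normal = p, p_spa = p, p = p, method = "normal",
             stringsAsFactors = FALSE)
}

test_that("candidate selection unions sources and enforces the MAF floor", {
  ids <- sprintf("v%02d", 1:6)
  overall <- fake_gwas_table(ids, c(1e-6, 1, 1, 1, 1e-9, 1))
  users <- fake_gwas_table(ids, c(1, 1e-7, 1, 1, 1, 1))
  nonusers <- fake_gwas_table(ids, c(1, 1, 1e-6, 1, 1, 1))
  overall$af[5] <- 0.005          # rare despite tiny p
  cand <- select_candidates(overall, users, nonusers)
  expect_setequal(cand$id, c("v01", "v02", "v03"))
  expect_identical(cand$discovery_source[cand$id == "v02"], "users")
  expect_identical(cand$discovery_source[cand$id == "v01"], "overall")
  # a variant suggestive in several sources carries all tags
  users2 <- users; users2$p[1] <- 1e-8
  cand2 <- select_candidates(overall, users2, nonusers)
  expect_identical(cand2$discovery_source[cand2$id == "v01"],
                   "overall,users")
  null_tab <- fake_gwas_table(ids, rep(0.5, 6))
  expect_warning(c0 <- select_candidates(null_tab, null_tab, null_tab),
                 "no candidate")
  expect_equal(nrow(c0), 0L)
})

test_that("Bonferroni threshold is alpha over the locus count", {
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(50), 1e-3)
  expect_equal(signif(bonferroni_threshold(178), 2), 2.8e-4)
  expect_error(bonferroni_threshold(0))
})

test_that("interaction coefficient is centred at zero under no interaction", {
  est <- vapply(1:25, function(r) {
    spec <- simulation_spec(n_samples = 2000, n_variants = 1,
                            maf_range = c(0.3, 0.300001),
                            baseline_hazard_rate = 0.012,
                            exposure_log_hr = log(0.92), seed = 6000 + r)
    g <- simulate_genotypes(spec)
    coh <- simulate_cohort(spec, g)
    test_interaction(g$variants$id[1], "fos", "dementia", "model1",
                     coh, g)$beta_int
  }, 0)
  expect_lt(abs(mean(est)), 3 * stats::sd(est) / sqrt(length(est)))
})

test_that("subgroup profiles flag sparse groups and mirror planted crossover", {
  ce <- data.frame(variant = 1, beta_main = log(0.77), beta_gxe = log(1.3 / 0.77))
  spec <- simulation_spec(n_samples = 15000, n_variants = 1,
                          maf_range = c(0.3, 0.300001),
                          baseline_hazard_rate = 0.008, causal_effects = ce,
                          covariate_log_hrs = NULL, exposure_log_hr = 0,
                          seed = 45)
  g <- simulate_genotypes(spec)
  coh <- simulate_cohort(spec, g)
  prof <- subgroup_hrs(g$variants$id[1], "fos", "dementia", coh, g)
  by_exp <- prof$hr_snp_by_exposure
  # dosage is protective among the unexposed, harmful among the exposed
  hr_exposed <- by_exp$hr[by_exp$exposure_level == 1]
  hr_unexposed <- by_exp$hr[by_exp$exposure_level == 0]
  expect_gt(hr_exposed, 1)
  expect_lt(hr_unexposed, 1)
  # a rare variant has no dosage-2 carriers: group flagged, not estimated
  G <- cbind(c(rep(1, 12), rep(0, 4988)))
  rare <- toy_genos(G)
  spec2 <- simulation_spec(n_samples = 5000, n_variants = 1,
                           baseline_hazard_rate = 0.01, seed = 46)
  coh2 <- simulate_cohort(spec2, simulate_genotypes(spec2))
  prof2 <- subgroup_hrs("v001", "fos", "dementia", coh2, rare)
  g2row <- prof2$hr_exposure_by_genotype
  expect_true(g2row$excluded[g2row$genotype == 2])
  expect_true(is.na(g2row$hr[g2row$genotype == 2]))
  # the dosage-1 group here has few events as well: the <=5 rule bites
  expect_true(g2row$excluded[g2row$genotype == 1] ||
                g2row$n_events[g2row$genotype == 1] > 5)
})

test_that("epsilon-4 positive control excludes ambiguous samples and has power", {
  spec <- simulation_spec(n_samples = 8000, n_variants = 1,
                          baseline_hazard_rate = 0.012, seed = 47)
  g <- simulate_genotypes(spec)
  coh <- simulate_cohort(spec, g)
  set.seed(48)
  coh$apoe_e4_dosage <- apoe_e4_dosage(
    sample(c("CC", "CT", "TT"), 8000, TRUE, c(0.04, 0.28, 0.68)),
    sample(c("CC", "CT", "TT"), 8000, TRUE, c(0.69, 0.28, 0.03)))
  n_excl <- sum(is.na(coh$apoe_e4_dosage))
  expect_gt(n_excl, 0)
  res <- apoe_positive_control(coh)
  expect_equal(res$n_used, 8000 - n_excl)
  # plant a strong e4-by-exposure effect by reweighting event times
  coh2 <- coh
  keep <- !is.na(coh2$apoe_e4_dosage)
  lp <- 0.6 * coh2$apoe_e4_dosage * coh2$fos
  set.seed(49)
  t_new <- rexp(nrow(coh2)) / (0.012 * exp(ifelse(keep, lp, 0)))
  coh2$event_dementia <- as.integer(t_new <= 13.8)
  coh2$time_years <- pmin(t_new, 13.8)
  res2 <- apoe_positive_control(coh2)
  expect_lt(res2$p_int, 0.05)
  expect_gt(res2$beta_int, 0)
  expect_error(apoe_positive_control(null_cohort(100)), "apoe_e4_dosage")
})

test_that("replication requires nominal significance and sign concordance", {
  ce <- data.frame(variant = 1, beta_main = 0, beta_gxe = 0.6)
  spec <- simulation_spec(n_samples = 8000, n_variants = 3,
                          maf_range = c(0.25, 0.35),
                          baseline_hazard_rate = 0.01, causal_effects = ce,
                          seed = 50)
  g <- simulate_genotypes(spec)
  coh <- simulate_cohort(spec, g)
  prim <- test_interaction(g$variants$id[1], "fos", "dementia", "model1",
                           coh, g)
  primary <- data.frame(variant_id = prim$variant_id, locus = "L1",
                        beta_int = prim$beta_int)
  # same exposure re-supplied: the significant locus replicates
  rep_same <- replicate_screen(primary, "fos", "dementia", "model1", coh, g)
  expect_true(rep_same$replicated)
  # a sign-flipped primary fails the concordance rule on the same data
  primary_flip <- primary
  primary_flip$beta_int <- -primary_flip$beta_int
  rep_flip <- replicate_screen(primary_flip, "fos", "dementia", "model1",
                               coh, g)
  expect_false(rep_flip$replicated)
  expect_true(rep_flip$sign_concordant == FALSE)
  # an exposure unrelated to the primary one rarely replicates null loci
  set.seed(51)
  coh$random_exposure <- rbinom(nrow(coh), 1, 0.4)
  null_primary <- data.frame(variant_id = g$variants$id[2:3],
                             locus = c("L2", "L3"),
                             beta_int = c(0.1, -0.1))
  rep_null <- replicate_screen(null_primary, "random_exposure", "dementia",
                               "model1", coh, g)
  expect_lte(sum(rep_null$replicated), 1)
})

test_that("cross-model comparison reports Pearson agreement", {
  tab <- data.frame(variant_id = sprintf("v%02d", 1:10),
                    beta_int = rnorm(10), p_int = runif(10, 1e-6, 1))
  same <- compare_models(list(model1 = tab, model2 = tab))
  expect_equal(same$r_beta, 1, tolerance = 1e-12)
  expect_equal(same$r_logp, 1, tolerance = 1e-12)
  expect_error(compare_models(list(model1 = tab[1:2, ], model2 = tab[1:2, ])),
               "3")
  # adding pure-noise adjustment barely moves interaction estimates
  ce <- data.frame(variant = c(1, 2, 3), beta_main = 0,
                   beta_gxe = c(0.4, -0.4, 0.2))
  spec <- simulation_spec(n_samples = 4000, n_variants = 12,
                          maf_range = c(0.2, 0.4),
                          baseline_hazard_rate = 0.012, causal_effects = ce,
                          seed = 52)
  g <- simulate_genotypes(spec)
  coh <- simulate_cohort(spec, g)
  runs <- lapply(c("model1", "model2"), function(mdl) {
    do.call(rbind, lapply(g$variants$id, function(v) {
      test_interaction(v, "fos", "dementia", mdl, coh, g)
    }))
  })
  names(runs) <- c("model1", "model2")
  cmp <- compare_models(runs)
  expect_gt(cmp$r_beta, 0.9)
  expect_gt(cmp$r_logp, 0.9)
})

test_that("subgroup preference test equals the exact binomial enumeration", {
  expect_equal(signif(subgroup_preference_test(13, 15), 2), 0.0074)
  expect_equal(signif(subgroup_preference_test(12, 15), 2), 0.035)
  expect_equal(subgroup_preference_test(15, 15), 2 * 0.5^15,
               tolerance = 1e-12)
  # exhaustive enumeration oracle for all n <= 30
  enum <- function(k, n) {
    probs <- dbinom(0:n, n, 0.5)
    sum(probs[probs <= probs[k + 1] * (1 + 1e-12)])
  }
  set.seed(53)
  for (i in 1:50) {
    n <- sample(1:30, 1)
    k <- sample(0:n, 1)
    expect_equal(subgroup_preference_test(k, n), enum(k, n),
                 tolerance = 1e-12, info = sprintf("k=%d n=%d", k, n))
  }
  expect_error(subgroup_preference_test(5, 4))
})

test_that("the full screen recovers a strong planted interaction locus", {
  ce <- data.frame(variant = 25, beta_main = 0, beta_gxe = 0.9)
  spec <- simulation_spec(n_samples = 8000, n_variants = 60,
                          ld_block_size = 10, ld_rho = 0.7,
                          maf_range = c(0.2, 0.4),
                          baseline_hazard_rate = 0.012, causal_effects = ce,
                          seed = 54)
  g <- simulate_genotypes(spec)
  coh <- simulate_cohort(spec, g)
  genes <- data.frame(chrom = "1", start = 230000, end = 260000,
                      symbol = "TARGET", biotype = "protein_coding")
  bundle <- run_screen(g, coh, screen_config(candidate_p = 1e-3),
                       genes = genes)
  expect_gte(bundle$n_loci, 1)
  expect_equal(bundle$threshold, 0.05 / bundle$n_loci)
  expect_true(any(bundle$interactions$significant))
  # the planted variant (or an LD partner in its block) is among the hits
  hit_ids <- bundle$significant$variant_id
  block <- g$variants$id[21:30]
  expect_true(any(hit_ids %in% block))
  expect_true(all(c("closest_gene", "gene_distance") %in%
                    names(bundle$significant)))
  expect_length(bundle$subgroup_profiles, nrow(bundle$significant))
})
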