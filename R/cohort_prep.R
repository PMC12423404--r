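#' Supplement-questionnaire vocabulary
#'
#' The declared option set for the baseline touchscreen supplement
#' question. Exposure coding rejects anything outside this vocabulary.
#'
#' @return Character vector of valid option labels.
#' @export
supplement_options <- function() {
  c("fish oil (including cod liver oil)", "glucosamine", "calcium", "zinc",
    "iron", "selenium", "vitamin", "mineral", "none of the above")
}

#' Derive fish-oil supplement status from questionnaire selections
#'
#' Returns 1 if the fish-oil option was selected, 0 if only other
#' supplements or "none of the above" were selected, and `NA` when the
#' question was not answered (empty selection).
#'
#' @param selected_options Character vector of selected options for one
#'   respondent, or a list of such vectors for many respondents.
#' @param vocabulary Valid option labels; unknown labels raise an error
#'   naming the label.
#' @return Integer 0/1 (or `NA`), vectorized over a list input.
#' @export
derive_fos_status <- function(selected_options,
                              vocabulary = supplement_options()) {
  if (is.list(selected_options)) {
    return(vapply(selected_options, derive_fos_status, integer(1),
                  vocabulary = vocabulary))
  }
  if (length(selected_options) == 0L) return(NA_integer_)
  unknown <- setdiff(selected_options, vocabulary)
  if (length(unknown)) {
    stop("unknown questionnaire option(s): ",
         paste(sQuote(unknown), collapse = ", "))
  }
  as.integer("fish oil (including cod liver oil)" %in% selected_options)
}

#' Oily-fish intake frequency levels
#' @return The six declared frequency categories, low to high.
#' @export
oily_fish_levels <- function() {
  c("never", "less than once a week", "once a week", "2-4 times a week",
    "5-6 times a week", "once or more daily")
}

#' Dichotomize oily-fish intake frequency
#'
#' "never" and "less than once a week" form the low-intake group (0); all
#' other levels form the high-intake group (1).
#'
#' @param frequency_level Character vector of levels from
#'   [oily_fish_levels()]; `NA` passes through.
#' @return Integer vector of 0/1 group codes.
#' @export
derive_oily_fish_group <- function(frequency_level) {
  lv <- oily_fish_levels()
  bad <- setdiff(frequency_level[!is.na(frequency_level)], lv)
  if (length(bad)) {
    stop("unknown oily fish intake level(s): ",
         paste(sQuote(unique(bad)), collapse = ", "))
  }
  ifelse(is.na(frequency_level), NA_integer_,
         as.integer(!frequency_level %in% c("never", "less than once a week")))
}

#' APOE epsilon-4 dosage from rs429358 and rs7412 genotypes
#'
#' Resolves the unphased two-SNP diplotype into epsilon haplotype pairs
#' using the haplotype definitions (rs429358, rs7412):
#' e2 = (T, T), e3 = (T, C), e4 = (C, C), e1 = (C, T), and counts e4
#' haplotypes. The double heterozygote (CT, CT) is ambiguous between
#' e1/e3 and e2/e4 and is excluded (`NA`, reason `"ambiguous"`); a
#' missing genotype at either SNP is excluded with reason `"missing"`.
#' Allele order within a genotype does not matter ("CT" == "TC").
#'
#' @param g_rs429358,g_rs7412 Character vectors of two-letter unphased
#'   genotypes over \{C, T\} (e.g. `"CT"`), `NA` for missing.
#' @return Integer vector of dosages 0/1/2 with `NA` for excluded
#'   samples; attribute `"reason"` holds `"ambiguous"`/`"missing"` per
#'   excluded element.
#' @export
apoe_e4_dosage <- function(g_rs429358, g_rs7412) {
  stopifnot(length(g_rs429358) == length(g_rs7412))
  norm <- function(g) {
    g <- toupper(g)
    ok <- !is.na(g)
    if (any(ok & !g %in% c("CC", "CT", "TC", "TT"))) {
      stop("genotypes must be unphased pairs over {C,T}")
    }
    g[g == "TC"] <- "CT"
    g
  }
  a <- norm(g_rs429358); b <- norm(g_rs7412)
  # rows: rs429358 in CC, CT, TT; cols: rs7412 in CC, CT, TT
  # haplotypes (rs429358, rs7412): e4=(C,C), e1=(C,T), e3=(T,C), e2=(T,T)
  tab <- matrix(c(2L, 1L, 0L,       # CC: e4/e4, e4/e1, e1/e1
                  1L, NA, 0L,       # CT: e4/e3, ambiguous, e1/e2
                  0L, 0L, 0L),      # TT: e3/e3, e3/e2, e2/e2
                nrow = 3, byrow = TRUE,
                dimnames = list(c("CC", "CT", "TT"), c("CC", "CT", "TT")))
  out <- rep(NA_integer_, length(a))
  reason <- rep(NA_character_, length(a))
  miss <- is.na(a) | is.na(b)
  reason[miss] <- "missing"
  ok <- !miss
  out[ok] <- tab[cbind(a[ok], b[ok])]
  reason[ok & is.na(out)] <- "ambiguous"
  attr(out, "reason") <- reason
  out
}

# classify a covariate column for the imputation model
impute_kind <- function(x) {
  if (is.factor(x) || is.character(x)) {
    if (length(unique(stats::na.omit(as.character(x)))) <= 2L) "binary" else "polytomous"
  } else if (is.logical(x) || all(stats::na.omit(x) %in% c(0, 1))) {
    "binary"
  } else {
    "continuous"
  }
}

#' Single chained-equations imputation of missing covariates
#'
#' Fills missing covariate values by chained equations: continuous
#' covariates via predictive mean matching (k nearest donors on the
#' linear-model prediction), binary covariates via logistic-regression
#' probability draws, and unordered categoricals via multinomial
#' logistic draws. Runs a fixed number of sweeps in ascending-missingness
#' visit order and returns a single completed table; observed values are
#' never changed. Deterministic given `seed`. Outcome and exposure
#' columns are assumed complete and are not touched.
#'
#' @param table Cohort data frame.
#' @param covariate_cols Columns eligible for imputation (default: the
#'   model-4 covariate set present in the table).
#' @param seed Integer seed.
#' @param k PMM donor count (default 5).
#' @param n_iter Chained-equation sweeps (default 10).
#' @return The completed data frame.
#' @export
impute_covariates <- function(table,
                              covariate_cols = intersect(model_covariates("model4"),
                                                         names(table)),
                              seed = 1L, k = 5L, n_iter = 10L) {
  miss_frac <- vapply(table[covariate_cols], function(x) mean(is.na(x)), 0)
  if (any(miss_frac == 1)) {
    stop("fully missing covariate(s): ",
         paste(covariate_cols[miss_frac == 1], collapse = ", "))
  }
  if (any(miss_frac > 0.5)) {
    warning("covariate(s) with >50% missing: ",
            paste(covariate_cols[miss_frac > 0.5], collapse = ", "))
  }
  to_impute <- covariate_cols[miss_frac > 0]
  if (length(to_impute) == 0L) return(table)
  to_impute <- to_impute[order(miss_frac[to_impute])]
  set.seed(seed)
  miss_idx <- lapply(table[to_impute], function(x) which(is.na(x)))
  names(miss_idx) <- to_impute
  # initialize by random draws from the observed values
  for (v in to_impute) {
    obs <- table[[v]][!is.na(table[[v]])]
    table[[v]][miss_idx[[v]]] <- sample(obs, length(miss_idx[[v]]), replace = TRUE)
  }
  for (iter in seq_len(n_iter)) {
    for (v in to_impute) {
      mi <- miss_idx[[v]]
      preds <- setdiff(covariate_cols, v)
      df <- table[, c(v, preds), drop = FALSE]
      names(df)[1] <- ".y"
      df_obs <- df[-mi, , drop = FALSE]
      kind <- impute_kind(table[[v]])
      if (kind == "continuous") {
        fit <- stats::lm(.y ~ ., data = df_obs)
        yhat_obs <- suppressWarnings(stats::predict(fit, df_obs))
        yhat_mis <- suppressWarnings(stats::predict(fit, df[mi, , drop = FALSE]))
        donors <- vapply(yhat_mis, function(yh) {
          d <- abs(yhat_obs - yh)
          cand <- order(d)[seq_len(min(k, length(d)))]
          df_obs$.y[sample(cand, 1L)]
        }, 0)
        table[[v]][mi] <- donors
      } else if (kind == "binary") {
        df_obs$.y <- as.integer(factor(df_obs$.y)) - 1L
        fit <- suppressWarnings(stats::glm(.y ~ ., data = df_obs,
                                           family = stats::binomial()))
        p1 <- suppressWarnings(stats::predict(fit, df[mi, , drop = FALSE],
                                              type = "response"))
        draw <- stats::rbinom(length(mi), 1L, p1)
        levs <- levels(factor(table[[v]][-mi]))
        if (is.numeric(table[[v]])) {
          table[[v]][mi] <- as.numeric(levs[draw + 1L])
        } else {
          table[[v]][mi] <- levs[draw + 1L]
        }
      } else {
        fit <- nnet::multinom(.y ~ ., data = df_obs, trace = FALSE)
        pr <- stats::predict(fit, df[mi, , drop = FALSE], type = "probs")
        if (is.null(dim(pr))) pr <- matrix(pr, nrow = length(mi))
        levs <- colnames(pr)
        if (is.null(levs)) levs <- fit$lev
        drawn <- apply(pr, 1, function(p) sample(levs, 1L, prob = p))
        if (is.factor(table[[v]])) {
          table[[v]][mi] <- factor(drawn, levels = levels(table[[v]]))
        } else {
          table[[v]][mi] <- drawn
        }
      }
    }
  }
  table
}
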