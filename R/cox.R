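#' Covariate presets for the interaction models
#'
#' Returns the covariate lists for the four nested Cox adjustment sets used
#' throughout the screen: `model1` adjusts for age, sex and the top 10
#' genetic principal components; `model2` adds socioeconomic and lifestyle
#' covariates (education, Townsend deprivation index, BMI, smoking, alcohol
#' intake, physical activity); `model3` adds eight dietary pattern
#' variables; `model4` adds five self-reported medical histories.
#'
#' @param model One of `"model1"`, `"model2"`, `"model3"`, `"model4"`.
#' @return Character vector of covariate column names.
#' @export
model_covariates <- function(model = c("model1", "model2", "model3", "model4")) {
  model <- match.arg(model)
  m1 <- c("age", "sex", paste0("pc", 1:10))
  m2 <- c(m1, "education", "tdi", "bmi", "smoking", "alcohol", "physical_activity")
  m3 <- c(m2, "diet_oily_fish", "diet_fruit", "diet_vegetable",
          "diet_processed_meat", "diet_red_meat", "suppl_vitamin",
          "suppl_mineral", "suppl_glucosamine")
  m4 <- c(m3, "hx_hypertension", "hx_cvd", "hx_high_cholesterol",
          "hx_diabetes", "hx_depression")
  switch(model, model1 = m1, model2 = m2, model3 = m3, model4 = m4)
}

#' Build a design matrix from covariate terms
#'
#' Expands a list of covariate names (optionally including `"a:b"` product
#' terms) into a numeric design matrix without intercept. Factors are dummy
#' coded. Constant columns and exact collinearity are detected and reported
#' by name rather than silently dropped.
#'
#' @param data Data frame holding the covariates.
#' @param terms Character vector of column names and optional product terms.
#' @return Numeric matrix with one row per row of `data`.
#' @export
build_design <- function(data, terms) {
  stopifnot(is.data.frame(data), length(terms) >= 1)
  fml <- stats::reformulate(terms)
  mf <- stats::model.frame(fml, data, na.action = stats::na.fail)
  X <- stats::model.matrix(fml, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  const <- apply(X, 2, function(v) max(v) == min(v))
  if (any(const)) {
    stop("constant column(s) in design: ", paste(colnames(X)[const], collapse = ", "))
  }
  qr_x <- qr(cbind(1, X))
  if (qr_x$rank < ncol(X) + 1L) {
    aliased <- colnames(X)[setdiff(seq_len(ncol(X) + 1L), qr_x$pivot[seq_len(qr_x$rank)]) - 1L]
    stop("collinear column(s) in design: ", paste(aliased, collapse = ", "))
  }
  X
}

# reverse cumulative sum: out[i] = sum(x[i:n])
revcumsum <- function(x) {
  rev(cumsum(rev(x)))
}

# Efron-tie-corrected log partial likelihood, gradient and information for
# centred design Xc sorted by increasing time. `first` holds, for each row,
# the first index of its tie group; `ev` the event row indices.
cox_ll_parts <- function(beta, Xc, status, first, ev, want = c("ll", "all")) {
  want <- match.arg(want)
  n <- nrow(Xc); p <- ncol(Xc)
  eta <- drop(Xc %*% beta)
  w <- exp(eta)
  rs_w <- revcumsum(w)[first]                       # risk-set sum aligned per row
  gkey <- first[ev]
  # tie groups among events
  d_by_key <- table(gkey)
  tied_keys <- as.integer(names(d_by_key)[d_by_key > 1L])
  singleton <- !(gkey %in% tied_keys)
  ev1 <- ev[singleton]

  ll <- sum(eta[ev1]) - sum(log(rs_w[ev1]))
  grad <- NULL; info <- NULL
  if (want == "all") {
    wX <- w * Xc
    rs_wX <- apply(wX, 2, function(col) revcumsum(col))[first, , drop = FALSE]
    # upper-triangle cross products for the information matrix
    ut <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
    wXX <- Xc[, ut[, 1], drop = FALSE] * Xc[, ut[, 2], drop = FALSE] * w
    rs_wXX <- apply(wXX, 2, function(col) revcumsum(col))[first, , drop = FALSE]
    mu1 <- rs_wX[ev1, , drop = FALSE] / rs_w[ev1]
    grad <- colSums(Xc[ev1, , drop = FALSE]) - colSums(mu1)
    m_flat <- colSums(rs_wXX[ev1, , drop = FALSE] / rs_w[ev1]) # E[xx'] part, flattened
    info <- matrix(0, p, p)
    info[cbind(ut[, 1], ut[, 2])] <- m_flat
    info[cbind(ut[, 2], ut[, 1])] <- m_flat
    info <- info - crossprod(mu1)
  }
  # Efron correction for tied event times
  for (f in tied_keys) {
    members <- ev[gkey == f]
    d <- length(members)
    k <- seq_len(d) - 1
    S_D <- sum(w[members]); S_R <- rs_w[f]
    denom <- S_R - (k / d) * S_D
    ll <- ll + sum(eta[members]) - sum(log(denom))
    if (want == "all") {
      U_D <- colSums(wX[members, , drop = FALSE]); U_R <- rs_wX[f, ]
      mu_k <- (outer(rep(1, d), U_R) - outer(k / d, U_D)) / denom     # d x p
      grad <- grad + colSums(Xc[members, , drop = FALSE]) - colSums(mu_k)
      M_D <- colSums(wXX[members, , drop = FALSE]); M_R <- rs_wXX[f, ]
      m_k <- (outer(rep(1, d), M_R) - outer(k / d, M_D)) / denom
      M_sum <- colSums(m_k)
      Mi <- matrix(0, p, p)
      Mi[cbind(ut[, 1], ut[, 2])] <- M_sum
      Mi[cbind(ut[, 2], ut[, 1])] <- M_sum
      info <- info + Mi - crossprod(mu_k)
    }
  }
  list(ll = ll, grad = grad, info = info, w = w)
}

#' Fit a Cox proportional hazards model
#'
#' Newton-Raphson maximization of the Efron-tie-corrected log partial
#' likelihood with step-halving, a small ridge fallback for near-singular
#' information matrices, Breslow baseline cumulative hazard and martingale
#' residuals \eqn{r_i = \delta_i - \hat\Lambda_0(t_i)\exp(x_i'\hat\beta)}.
#' The time scale is time-on-study; delayed entry is not modelled.
#'
#' @param cohort Data frame with a `time_years` column, an
#'   `event_<outcome>` column, and all covariates named in `terms`.
#' @param terms Character vector of covariate names; `"a:b"` adds a product
#'   term.
#' @param outcome Outcome label, e.g. `"dementia"` selects
#'   `event_dementia`.
#' @param eps Convergence tolerance on the relative log-likelihood change.
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `cox_fit`: `beta`, `cov`, `loglik`,
#'   `loglik_null`, `n`, `n_events`, `converged`, `iterations`,
#'   `cum_baseline_hazard` (step function over event times),
#'   `martingale_residuals` (original row order), `terms`, `outcome`,
#'   and the design matrix `X`.
#' @export
fit_cox <- function(cohort, terms, outcome = "dementia",
                    eps = 1e-9, max_iter = 50L) {
  ev_col <- paste0("event_", outcome)
  if (!ev_col %in% names(cohort)) stop("no column ", ev_col, " in cohort")
  if (!"time_years" %in% names(cohort)) stop("no time_years column in cohort")
  time <- cohort$time_years
  status <- as.integer(cohort[[ev_col]])
  if (any(time <= 0)) stop("all follow-up times must be positive")
  if (sum(status) < 1L) stop("no events for outcome ", outcome)
  X <- build_design(cohort, terms)
  fit <- cox_fit_matrix(X, time, status, eps = eps, max_iter = max_iter)
  fit$terms <- terms
  fit$outcome <- outcome
  fit
}

#' Fit a Cox model from a raw design matrix
#'
#' Lower-level entry point behind [fit_cox()]: takes an already-built
#' numeric design matrix instead of a cohort table.
#'
#' @param X Numeric design matrix (no intercept).
#' @param time Positive follow-up times.
#' @param status 0/1 event indicators.
#' @inheritParams fit_cox
#' @return See [fit_cox()].
#' @export
cox_fit_matrix <- function(X, time, status, eps = 1e-9, max_iter = 50L) {
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(time) == n, length(status) == n)
  ctr <- colMeans(X)
  ord <- order(time)
  Xc <- sweep(X[ord, , drop = FALSE], 2, ctr)
  t_s <- time[ord]; st_s <- status[ord]
  first <- match(t_s, t_s)
  ev <- which(st_s == 1L)

  beta <- rep(0, p)
  parts <- cox_ll_parts(beta, Xc, st_s, first, ev, want = "all")
  ll0 <- parts$ll
  ll <- parts$ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(parts$info, parts$grad),
                     error = function(e) solve(parts$info + diag(1e-8, p), parts$grad))
    # step-halving line search: partial likelihood must not decrease
    halve <- 0L
    repeat {
      cand <- beta + step
      ll_new <- cox_ll_parts(cand, Xc, st_s, first, ev, want = "ll")$ll
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      halve <- halve + 1L
      if (halve > 30L) break
    }
    beta <- beta + step
    if (any(abs(beta) > 20)) {
      stop("monotone partial likelihood (separation) for at least one term; ",
           "consider penalized estimation or removing the term")
    }
    parts <- cox_ll_parts(beta, Xc, st_s, first, ev, want = "all")
    if (abs(parts$ll - ll) < eps * (abs(ll) + 0.1)) {
      ll <- parts$ll
      converged <- TRUE
      break
    }
    ll <- parts$ll
  }
  cov <- tryCatch(solve(parts$info),
                  error = function(e) solve(parts$info + diag(1e-8, p)))
  dimnames(cov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  # Breslow baseline cumulative hazard on the centred linear predictor scale
  w <- parts$w
  rs_w <- revcumsum(w)[first]
  gkey <- first[ev]
  d_at <- tapply(rep(1L, length(ev)), gkey, sum)
  inc <- numeric(n)
  inc[as.integer(names(d_at))] <- as.numeric(d_at) / rs_w[as.integer(names(d_at))]
  Lam_sorted <- cumsum(inc)                         # Lambda0 at each subject's own time
  resid_sorted <- st_s - Lam_sorted * w
  resid <- numeric(n); resid[ord] <- resid_sorted

  ev_first <- sort(unique(gkey))
  base <- data.frame(time = t_s[ev_first], cum_hazard = Lam_sorted[ev_first])

  structure(list(
    beta = beta, cov = cov, loglik = ll, loglik_null = ll0,
    n = n, n_events = sum(st_s), converged = converged, iterations = iter,
    cum_baseline_hazard = base, martingale_residuals = resid,
    center = ctr, X = X, time = time, status = status
  ), class = "cox_fit")
}

#' @method print cox_fit
#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional hazards fit (Efron ties)\n")
  cat(sprintf("  n = %d, events = %d, iterations = %d, converged = %s\n",
              x$n, x$n_events, x$iterations, x$converged))
  se <- sqrt(diag(x$cov))
  print(data.frame(beta = x$beta, hr = exp(x$beta), se = se), digits = 4)
  invisible(x)
}

#' Wald test for a single model term
#'
#' Normal-approximation inference on the log hazard-ratio scale:
#' \eqn{z = \hat\beta/\mathrm{SE}}, two-sided p, and a 95\% confidence
#' interval \eqn{\exp(\hat\beta \pm 1.96\,\mathrm{SE})}.
#'
#' @param fit A `cox_fit`.
#' @param term Coefficient name (a column of the design matrix).
#' @return Data frame row: `term`, `beta`, `se`, `z`, `p`, `hr`,
#'   `hr_lo`, `hr_hi`.
#' @export
wald_test <- function(fit, term) {
  if (!term %in% names(fit$beta)) {
    stop("term '", term, "' not in model (have: ",
         paste(names(fit$beta), collapse = ", "), ")")
  }
  b <- unname(fit$beta[term])
  se <- sqrt(fit$cov[term, term])
  z <- b / se
  data.frame(term = term, beta = b, se = se, z = z,
             p = 2 * stats::pnorm(-abs(z)),
             hr = exp(b),
             hr_lo = exp(b - stats::qnorm(0.975) * se),
             hr_hi = exp(b + stats::qnorm(0.975) * se))
}

#' Likelihood-ratio test of nested Cox models
#'
#' Chi-squared test on twice the log partial-likelihood difference, with
#' degrees of freedom equal to the difference in coefficient counts.
#'
#' @param full,reduced `cox_fit` objects on the same samples; the reduced
#'   model's terms must be a subset of the full model's.
#' @return Two-sided p-value.
#' @export
lrt <- function(full, reduced) {
  if (full$n != reduced$n || full$n_events != reduced$n_events) {
    stop("models fitted on different samples")
  }
  if (!all(names(reduced$beta) %in% names(full$beta))) {
    stop("models are not nested: reduced terms must be a subset of full terms")
  }
  df <- length(full$beta) - length(reduced$beta)
  if (df == 0L) return(1)
  stat <- 2 * (full$loglik - reduced$loglik)
  stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}
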