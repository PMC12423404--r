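# Shared fixture builders for the test suite. Everything is generated in
# code at test time; sizes are kept small except where a check's stated
# conditions require otherwise.

# A small null survival cohort (no genetic signal) for score-test and
# Cox-engine checks.
null_cohort <- function(n, event_frac = 0.1, seed = 1, p_covars = TRUE) {
  set.seed(seed)
  df <- data.frame(
    time_years = stats::runif(n, 0.5, 13.8),
    event_dementia = stats::rbinom(n, 1, event_frac),
    age = stats::rnorm(n, 56.8, 8),
    sex = stats::rbinom(n, 1, 0.5))
  if (p_covars) {
    pcs <- matrix(stats::rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("pc", 1:10)))
    df <- cbind(df, pcs)
  }
  df
}

# Brute-force partial-likelihood value for untied right-censored data
# (Breslow = Efron when there are no ties); independent of the package's
# Newton-Raphson path.
grid_partial_loglik <- function(beta, x, time, status) {
  ord <- order(time)
  x <- x[ord]; status <- status[ord]
  eta <- beta * x
  w <- exp(eta)
  rs <- rev(cumsum(rev(w)))
  sum((eta - log(rs))[status == 1])
}

# Direct-formula HWE enumeration oracle (log-gamma arithmetic), fully
# independent of the package's recurrence implementation.
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  n_rare <- min(n_a, 2 * n - n_a)
  if (n_rare == 0) return(1)
  h_min <- n_rare %% 2
  hs <- seq(h_min, min(n_rare, 2 * n - n_rare), by = 2)
  logp <- vapply(hs, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) -
      lgamma(2 * n + 1)
  }, 0)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

# Exhaustive greedy-clumping oracle on a precomputed r-squared matrix,
# written directly from the stated membership rule.
clump_oracle <- function(tab, r2mat, p_thr, r2_thr, window) {
  sig <- tab[tab$p < p_thr, , drop = FALSE]
  sig <- sig[order(sig$p, sig$pos, sig$id), , drop = FALSE]
  idx <- character(0)
  assign <- character(nrow(sig))
  for (i in seq_len(nrow(sig))) {
    hit <- NA_character_
    for (ix in idx) {
      row_ix <- sig[sig$id == ix, ]
      if (row_ix$chrom == sig$chrom[i] &&
          abs(row_ix$pos - sig$pos[i]) <= window &&
          r2mat[ix, sig$id[i]] >= r2_thr) {
        hit <- ix
        break
      }
    }
    if (is.na(hit)) {
      idx <- c(idx, sig$id[i])
      assign[i] <- sig$id[i]
    } else {
      assign[i] <- hit
    }
  }
  split(sig$id, assign)
}

# Build a genotype_matrix from a raw dosage matrix with evenly spaced
# positions on one chromosome.
toy_genos <- function(G, pos = NULL, chrom = "1") {
  m <- ncol(G)
  if (is.null(pos)) pos <- 1L + (seq_len(m) - 1L) * 10000L
  af <- colMeans(G, na.rm = TRUE) / 2
  genotype_matrix(
    G,
    data.frame(chrom = chrom, pos = pos,
               id = sprintf("v%03d", seq_len(m)), ref = "A", alt = "G",
               maf = pmin(af, 1 - af), info = 1,
               call_rate = colMeans(!is.na(G)),
               hwe_p = 1, stringsAsFactors = FALSE),
    sprintf("S%04d", seq_len(nrow(G))))
}
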