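# Independent oracle implementations used to cross-check the package.
# These deliberately use direct/naive formulations (full enumeration, double
# loops) rather than the implementation's algorithms.

# Exact HWE p-value by direct evaluation of every heterozygote count's
# conditional probability from log-factorials (no recurrence).
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  n_a <- 2 * n_aa + n_Aa
  if (min(n_A, n_a) == 0) return(1)
  h_vals <- seq.int(min(n_A, n_a) %% 2, min(n_A, n_a), by = 2)
  logp <- vapply(h_vals, function(h) {
    aa <- (n_A - h) / 2
    bb <- (n_a - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(n_A) + lfactorial(n_a) - lfactorial(2 * n)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[h_vals == n_Aa]
  sum(prob[prob <= obs * (1 + 1e-10)])
}

# Greedy P+T clumping, written as a naive full-scan loop over a dense r2
# matrix (no windows, no precomputed ordering structures).
oracle_clump <- function(p, chrom, pos, r2mat, p_threshold, r2_threshold) {
  m <- length(p)
  selected <- logical(m)
  removed <- logical(m)
  repeat {
    cand <- which(!selected & !removed & p <= p_threshold)
    if (!length(cand)) break
    ord <- cand[order(p[cand], chrom[cand], pos[cand])]
    i <- ord[1]
    selected[i] <- TRUE
    for (j in seq_len(m)) {
      if (!selected[j] && !removed[j] && j != i && r2mat[i, j] > r2_threshold) {
        removed[j] <- TRUE
      }
    }
  }
  which(selected)
}

# Brute-force PGS: explicit double loop over samples and matched variants.
oracle_score <- function(dosages, weights_df, variants_df) {
  n <- nrow(dosages)
  raw <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (k in seq_len(nrow(weights_df))) {
      j <- match(weights_df$variant_id[k], variants_df$id)
      if (is.na(j)) next
      d <- dosages[i, j]
      if (variants_df$effect_allele[j] == weights_df$effect_allele[k] &&
          variants_df$other_allele[j] == weights_df$other_allele[k]) {
        # as-is
      } else if (variants_df$effect_allele[j] == weights_df$other_allele[k] &&
                 variants_df$other_allele[j] == weights_df$effect_allele[k]) {
        d <- 2 - d
      } else {
        next
      }
      if (is.na(d)) {
        col <- dosages[, j]
        if (variants_df$effect_allele[j] == weights_df$other_allele[k]) col <- 2 - col
        d <- mean(col, na.rm = TRUE)
      }
      s <- s + d * weights_df$weight[k]
    }
    raw[i] <- s
  }
  raw
}

# Direct-formula fixed-effect and DerSimonian-Laird pooling.
oracle_fixed <- function(theta, se) {
  w <- 1 / se^2
  est <- sum(w * theta) / sum(w)
  list(estimate = est, se = sqrt(1 / sum(w)),
       Q = sum(w * (theta - est)^2))
}
oracle_random <- function(theta, se) {
  f <- oracle_fixed(theta, se)
  w <- 1 / se^2
  df <- length(theta) - 1
  tau2 <- max(0, (f$Q - df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(estimate = sum(ws * theta) / sum(ws), se = sqrt(1 / sum(ws)), tau2 = tau2)
}

# O(n^2) Spearman correlation from the definition (Pearson on midranks,
# computed by pairwise comparison counts).
oracle_spearman <- function(x, y) {
  n <- length(x)
  rank_naive <- function(v) {
    vapply(seq_len(n), function(i) {
      1 + sum(v < v[i]) + (sum(v == v[i]) - 1) / 2
    }, numeric(1))
  }
  rx <- rank_naive(x); ry <- rank_naive(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Closed-form two-component posterior inclusion probability for a single
# observation under the spike-and-slab prior, via the Bayes factor.
oracle_pip <- function(beta, n, rho, sigma2) {
  bf <- dnorm(beta, 0, sqrt(sigma2 + 1 / n)) / dnorm(beta, 0, sqrt(1 / n))
  rho * bf / (rho * bf + (1 - rho))
}

# Analytic two-sided power of a fixed-effect meta z-test at the pooled SE.
oracle_fixed_power <- function(log_or, se_pooled, alpha = 0.05) {
  z <- qnorm(1 - alpha / 2)
  lam <- log_or / se_pooled
  pnorm(lam - z) + pnorm(-lam - z)
}
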