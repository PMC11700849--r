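#' Infinitesimal-model shrinkage weights
#'
#' Closed-form joint-effect estimate under the infinitesimal model: per LD
#' window, `w = (R + (M / (n * h2)) I)^-1 beta_marginal`, where `R` is the
#' window LD matrix and `M` the total number of variants in the model. With
#' identity LD this reduces to elementwise shrinkage
#' `w_j = beta_j * n * h2 / (n * h2 + M)`.
#'
#' @param ss A `summary_stats` data.frame.
#' @param ld An [ld_reference()].
#' @param h2 Assumed trait heritability in `(0, 1)`.
#' @param n GWAS sample size used for the summary statistics.
#' @param model_id Optional model identifier.
#' @return A `pgs_model` with method `"ldpred_inf"`.
#' @export
ldpred_inf <- function(ss, ld, h2, n, model_id = "ldpred_inf") {
  stopifnot(h2 > 0, h2 < 1, n > 0)
  al <- align_sumstats(ss, ld)
  m_total <- nrow(al)
  lambda <- m_total / (n * h2)
  w <- numeric(m_total)
  win <- ld$window[al$ld_index]
  local <- al$ld_index - ld$window_start[as.character(win)] + 1L
  for (wid in unique(win)) {
    members <- which(win == wid)
    R <- ld$R[[as.character(wid)]][local[members], local[members], drop = FALSE]
    sol <- tryCatch(
      solve(R + diag(lambda, length(members)), al$beta_marginal[members]),
      error = function(e) {
        stop(sprintf("singular LD system in window %s despite ridge term: %s",
                     wid, conditionMessage(e)), call. = FALSE)
      }
    )
    w[members] <- sol
  }
  new_pgs_model(model_id, "ldpred_inf",
                list(h2 = h2, n = n),
                weights_frame(al, w))
}

#' Posterior inclusion probability under the point-normal prior
#'
#' For a residualized marginal effect `beta_tilde` with sampling variance
#' `1/n`, a spike-and-slab prior (causal with probability `rho`, causal
#' variance `sigma2`) gives inclusion probability
#' `rho f1 / (rho f1 + (1 - rho) f0)` with `f1 = N(beta_tilde; 0, sigma2 +
#' 1/n)` and `f0 = N(beta_tilde; 0, 1/n)`. Evaluated in log space. This is
#' the per-variant update used inside [ldpred_gibbs()].
#'
#' @param beta_tilde Residualized marginal effect(s).
#' @param n GWAS sample size.
#' @param rho Prior causal probability in `(0, 1]`.
#' @param sigma2 Prior causal-effect variance.
#' @return Inclusion probabilities in `[0, 1]` (1 when `rho == 1`).
#' @export
ldpred_pip <- function(beta_tilde, n, rho, sigma2) {
  stopifnot(rho > 0, rho <= 1, n > 0, sigma2 > 0)
  if (rho == 1) return(rep(1, length(beta_tilde)))
  l1 <- log(rho) + dnorm(beta_tilde, 0, sqrt(sigma2 + 1 / n), log = TRUE)
  l0 <- log(1 - rho) + dnorm(beta_tilde, 0, sqrt(1 / n), log = TRUE)
  1 / (1 + exp(l0 - l1))
}

#' Point-normal Gibbs shrinkage weights
#'
#' Per LD window, Gibbs sampling of the point-normal posterior: the prior is
#' causal with probability `rho` and causal variance `h2 / (M * rho)` (`M` =
#' total model variants), so total genetic variance is `h2` regardless of
#' `rho`. Each sweep residualizes every variant's marginal effect against the
#' current sampled effects of the others through the window LD matrix,
#' computes its posterior inclusion probability ([ldpred_pip()]), and samples
#' the effect. The final weight is the posterior mean over post-burn-in
#' sweeps. At `rho = 1` the sampler targets the infinitesimal posterior and
#' agrees with [ldpred_inf()] up to Monte-Carlo error.
#'
#' @inheritParams ldpred_inf
#' @param rho Causal fraction in `(0, 1]`.
#' @param n_iter Total Gibbs sweeps.
#' @param burnin Burn-in sweeps discarded from the average (`n_iter > burnin`).
#' @param seed Integer seed; identical seeds give identical weights.
#' @return A `pgs_model` with method `"ldpred_grid"`; the weights table also
#'   carries a per-variant posterior `inclusion` frequency. Errors if the
#'   sampler diverges (mean absolute weight exceeding 10x the mean absolute
#'   marginal effect).
#' @export
ldpred_gibbs <- function(ss, ld, rho, h2, n, n_iter = 600L, burnin = 100L,
                         seed = 1L, model_id = sprintf("ldpred_rho%g", rho)) {
  stopifnot(rho > 0, rho <= 1, h2 > 0, h2 < 1, n > 0,
            n_iter > burnin, burnin >= 0)
  al <- align_sumstats(ss, ld)
  m_total <- nrow(al)
  sigma2 <- h2 / (m_total * rho)
  set.seed(as.integer(seed))

  w <- numeric(m_total)
  incl <- numeric(m_total)
  win <- ld$window[al$ld_index]
  local <- al$ld_index - ld$window_start[as.character(win)] + 1L
  for (wid in unique(win)) {
    members <- which(win == wid)
    R <- ld$R[[as.character(wid)]][local[members], local[members], drop = FALSE]
    res <- gibbs_window_cpp(R, al$beta_marginal[members], n, rho, sigma2,
                            as.integer(n_iter), as.integer(burnin))
    w[members] <- res$weight
    incl[members] <- res$inclusion
  }
  if (mean(abs(w)) > 10 * mean(abs(al$beta_marginal))) {
    stop(sprintf(
      "Gibbs sampler diverged for %s: mean |weight| = %.3g vs mean |beta| = %.3g",
      model_id, mean(abs(w)), mean(abs(al$beta_marginal))), call. = FALSE)
  }
  wf <- weights_frame(al, w)
  wf$inclusion <- incl
  new_pgs_model(model_id, "ldpred_grid",
                list(rho = rho, h2 = h2, n = n, n_iter = as.integer(n_iter),
                     burnin = as.integer(burnin), seed = as.integer(seed)),
                wf)
}

#' Build the point-normal model grid over causal fractions
#'
#' One Gibbs model per value of `rho_grid` (default: the seven-value grid
#' 1, 0.3, 0.1, 0.03, 0.01, 0.003, 0.001), sharing `h2` and `n`.
#'
#' @inheritParams ldpred_gibbs
#' @param rho_grid Numeric vector of causal fractions.
#' @return A `pgs_model_grid` (list of `pgs_model`), one per rho.
#' @export
build_ldpred_grid <- function(ss, ld, h2, n,
                              rho_grid = c(1, 0.3, 0.1, 0.03, 0.01, 0.003, 0.001),
                              n_iter = 600L, burnin = 100L, seed = 1L) {
  out <- vector("list", length(rho_grid))
  for (i in seq_along(rho_grid)) {
    out[[i]] <- ldpred_gibbs(ss, ld, rho = rho_grid[i], h2 = h2, n = n,
                             n_iter = n_iter, burnin = burnin,
                             seed = as.integer(seed) + i)
  }
  names(out) <- vapply(out, `[[`, character(1), "model_id")
  structure(out, class = "pgs_model_grid")
}
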