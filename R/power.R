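#' Simulation-based power for a multi-cohort meta-analysis
#'
#' Estimates, for each (heterogeneity I^2, odds ratio) grid cell, the power
#' of a k-study inverse-variance meta-analysis with the heterogeneity-
#' triggered random-effects fallback ([auto_meta()]). The default design is
#' three validation cohorts of 50,195 / 11,947 / 6,796 individuals tested
#' two-sided at alpha = 0.05, over I^2 in \{0, 0.2, 0.4, 0.6, 0.8\} and OR
#' from 1.01 to 1.08 in steps of 0.01.
#'
#' Within-study variances use the balanced 2x2 approximation
#' `var(logOR) = (4 / n_i) * (1 / prevalence + 1 / (1 - prevalence))`
#' (two equal exposure groups, outcome prevalence applied to both); I^2 is
#' converted to a between-study variance through
#' `tau2 = I2 / (1 - I2) * v_bar` with `v_bar` the mean within-study
#' variance. Each simulation draws true study effects `N(log OR, tau2)`,
#' observed effects `N(true, v_i)`, runs [auto_meta()], and power is the
#' fraction of simulations with pooled `p < alpha`.
#'
#' @param n_per_study Integer vector of per-study sample sizes (length k).
#' @param prevalence Outcome prevalence used in the variance approximation.
#' @param or_grid Odds-ratio grid.
#' @param i2_grid I^2 grid (values in `[0, 1)`).
#' @param alpha Two-sided significance level.
#' @param n_sim Simulations per cell (>= 100).
#' @param seed Integer seed; the grid is reproducible given the seed.
#' @return Data.frame of class `power_grid`: i2, or, power, mc_se (binomial
#'   Monte-Carlo SE), with the design stored in attributes `design`.
#' @export
power_simulation <- function(n_per_study = c(50195, 11947, 6796),
                             prevalence = 0.3,
                             or_grid = seq(1.01, 1.08, by = 0.01),
                             i2_grid = c(0, 0.2, 0.4, 0.6, 0.8),
                             alpha = 0.05,
                             n_sim = 1000L,
                             seed = 1L) {
  stopifnot(n_sim >= 100L, all(i2_grid >= 0), all(i2_grid < 1),
            all(or_grid > 0), prevalence > 0, prevalence < 1,
            length(n_per_study) >= 2L)
  set.seed(as.integer(seed))
  k <- length(n_per_study)
  v <- (4 / n_per_study) * (1 / prevalence + 1 / (1 - prevalence))
  se_i <- sqrt(v)
  v_bar <- mean(v)

  cells <- expand.grid(i2 = i2_grid, or = or_grid, KEEP.OUT.ATTRS = FALSE)
  power <- numeric(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    tau2 <- cells$i2[ci] / (1 - cells$i2[ci]) * v_bar
    mu <- log(cells$or[ci])
    hits <- 0L
    for (s in seq_len(n_sim)) {
      theta <- rnorm(k, mu, sqrt(tau2))
      obs <- rnorm(k, theta, se_i)
      res <- auto_meta(study_effects(paste0("s", seq_len(k)), obs, se_i))
      if (res$p < alpha) hits <- hits + 1L
    }
    power[ci] <- hits / n_sim
  }
  out <- data.frame(i2 = cells$i2, or = cells$or, power = power,
                    mc_se = sqrt(power * (1 - power) / n_sim))
  attr(out, "design") <- list(k = k, n_per_study = n_per_study,
                              prevalence = prevalence, alpha = alpha,
                              sidedness = "two-sided", n_sim = n_sim)
  class(out) <- c("power_grid", "data.frame")
  out
}
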