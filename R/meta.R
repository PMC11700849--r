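#' Study effects container
#'
#' Convenience constructor for per-cohort log odds ratios entering a
#' meta-analysis.
#'
#' @param study_id Character study labels.
#' @param log_or Numeric log odds ratios.
#' @param se Positive standard errors.
#' @param n Optional per-study sample sizes.
#' @return Data.frame of class `study_effects`.
#' @export
study_effects <- function(study_id, log_or, se, n = NA_integer_) {
  stopifnot(length(study_id) == length(log_or), length(log_or) == length(se),
            all(se > 0))
  out <- data.frame(study_id = as.character(study_id), log_or = log_or,
                    se = se, n = n, stringsAsFactors = FALSE)
  class(out) <- c("study_effects", "data.frame")
  out
}

new_meta_result <- function(estimate, se, z, p, Q, df, p_het, i2, tau2, model_used, k) {
  structure(list(
    estimate = estimate, se = se,
    ci_low = estimate - 1.96 * se, ci_high = estimate + 1.96 * se,
    z = z, p = p, Q = Q, df = df, p_het = p_het,
    i2 = i2, tau2 = tau2, model_used = model_used, k = k
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "<meta_result> %s-effect pooling of %d studies\n  OR = %.3f [%.3f-%.3f], p = %.3g; Q = %.3f (df %d, p_het = %s), I2 = %.2f, tau2 = %.4g\n",
    x$model_used, x$k, exp(x$estimate), exp(x$ci_low), exp(x$ci_high), x$p,
    x$Q, x$df, format(x$p_het, digits = 3), x$i2, x$tau2))
  invisible(x)
}

heterogeneity <- function(theta, w) {
  pooled <- sum(w * theta) / sum(w)
  Q <- sum(w * (theta - pooled)^2)
  df <- length(theta) - 1L
  p_het <- if (df > 0) pchisq(Q, df, lower.tail = FALSE) else NA_real_
  i2 <- if (Q > 0) max(0, (Q - df) / Q) else 0
  list(pooled = pooled, Q = Q, df = df, p_het = p_het, i2 = i2)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Weights `w_i = 1 / se_i^2`; pooled estimate `sum(w theta) / sum(w)` with
#' `SE = 1 / sqrt(sum(w))`; Cochran's `Q`, its chi-square heterogeneity
#' p-value, and `I^2 = max(0, (Q - df) / Q)` are reported alongside.
#' Two-sided normal inference on the pooled log-OR.
#'
#' @param effects A `study_effects` data.frame (k >= 1).
#' @return A `meta_result` with `model_used = "fixed"` and `tau2 = 0`.
#' @export
fixed_meta <- function(effects) {
  stopifnot(nrow(effects) >= 1L, all(effects$se > 0))
  w <- 1 / effects$se^2
  het <- heterogeneity(effects$log_or, w)
  se <- 1 / sqrt(sum(w))
  z <- het$pooled / se
  new_meta_result(het$pooled, se, z, 2 * pnorm(-abs(z)),
                  het$Q, het$df, het$p_het, het$i2, 0, "fixed", nrow(effects))
}

#' Random-effects meta-analysis (DerSimonian-Laird)
#'
#' Between-study variance `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2) /
#' sum(w)))` from fixed-effect weights, then inverse-variance pooling with
#' weights `1 / (se_i^2 + tau2)`. Heterogeneity statistics (`Q`, `I^2`,
#' `p_het`) are those of the fixed-effect weights.
#'
#' @param effects A `study_effects` data.frame (k >= 2).
#' @return A `meta_result` with `model_used = "random"`.
#' @export
random_meta <- function(effects) {
  stopifnot(nrow(effects) >= 2L, all(effects$se > 0))
  w <- 1 / effects$se^2
  het <- heterogeneity(effects$log_or, w)
  tau2 <- max(0, (het$Q - het$df) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (effects$se^2 + tau2)
  pooled <- sum(w_star * effects$log_or) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  z <- pooled / se
  new_meta_result(pooled, se, z, 2 * pnorm(-abs(z)),
                  het$Q, het$df, het$p_het, het$i2, tau2, "random", nrow(effects))
}

#' Fixed-effect meta-analysis with random-effects fallback
#'
#' Pools with the fixed-effect model unless the heterogeneity test is
#' significant (`p_het < het_alpha`, strict inequality), in which case the
#' DerSimonian-Laird random-effects model is used. `model_used` records the
#' choice.
#'
#' @param effects A `study_effects` data.frame (k >= 2).
#' @param het_alpha Significance level of the heterogeneity test.
#' @return A `meta_result`.
#' @export
auto_meta <- function(effects, het_alpha = 0.05) {
  stopifnot(nrow(effects) >= 2L)
  fixed <- fixed_meta(effects)
  if (!is.na(fixed$p_het) && fixed$p_het < het_alpha) random_meta(effects) else fixed
}
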