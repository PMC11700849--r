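#' Score individuals against a PGS model
#'
#' `raw_score_i = sum_j dosage_ij * w_j` over model variants present in the
#' panel. Allele reconciliation per variant: exact effect/other match is used
#' as-is; swapped alleles flip the dosage to `2 - dosage`; any other allele
#' pair is skipped and counted. Missing dosages are mean-imputed from the
#' panel (per variant) by default.
#'
#' @param panel A `genotype_panel`.
#' @param model A `pgs_model`.
#' @param cohort_id Cohort label attached to the scores (scalar or
#'   per-sample vector).
#' @param missing `"mean"` (impute missing dosages at the observed per-variant
#'   mean) or `"fail"` (error on any missing dosage among matched variants).
#' @return A data.frame of class `score_set`: sample_id, cohort_id, raw_score,
#'   z_score (`NA` until [normalize_scores()]), n_alleles_used. Attributes
#'   `n_matched`, `n_flipped`, `n_skipped` summarize allele reconciliation.
#' @examples
#' cfg <- sim_config(n_variants = 30, n_blocks = 3, cohort_sizes = c(100, 100))
#' panel <- simulate_panel(cfg, 50, seed = 1)
#' eff <- simulate_effects(cfg, seed = 2)
#' ph <- simulate_phenotypes(panel, eff, cfg, "c1", seed = 3)
#' ss <- simulate_gwas(panel, ph)
#' ld <- ld_reference(panel, window_size = 10)
#' model <- clump_threshold(ss, ld, 1, 0.8)
#' head(pgs_score(panel, model))
#' @export
pgs_score <- function(panel, model, cohort_id = "cohort1",
                      missing = c("mean", "fail")) {
  missing <- match.arg(missing)
  w <- model$weights
  idx <- match(w$variant_id, panel$variants$id)
  present <- !is.na(idx)
  if (!any(present)) stop("no model variant found in the panel", call. = FALSE)
  w <- w[present, , drop = FALSE]
  idx <- idx[present]

  pv <- panel$variants[idx, , drop = FALSE]
  same <- pv$effect_allele == w$effect_allele & pv$other_allele == w$other_allele
  flip <- pv$effect_allele == w$other_allele & pv$other_allele == w$effect_allele
  skip <- !(same | flip)
  n_skipped <- sum(skip) + sum(!present)
  use <- which(!skip)
  if (length(use) == 0L) stop("no model variant matched on alleles", call. = FALSE)

  x <- panel$dosages[, idx[use], drop = FALSE]
  fl <- flip[use]
  if (any(fl)) x[, fl] <- 2 - x[, fl]
  if (anyNA(x)) {
    if (missing == "fail") stop("missing dosages among matched variants", call. = FALSE)
    cm <- colMeans(x, na.rm = TRUE)
    nas <- which(is.na(x), arr.ind = TRUE)
    x[nas] <- cm[nas[, 2]]
  }
  raw <- drop(x %*% w$weight[use])

  out <- data.frame(
    sample_id = panel$samples$sample_id,
    cohort_id = cohort_id,
    raw_score = raw,
    z_score = NA_real_,
    n_alleles_used = 2L * length(use),
    stringsAsFactors = FALSE
  )
  class(out) <- c("score_set", "data.frame")
  attr(out, "n_matched") <- length(use)
  attr(out, "n_flipped") <- sum(fl)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Normalize PGS values per cohort or pooled
#'
#' `z = (raw - mean) / sd` within each normalization unit, with the sample
#' (n-1) SD. `per_cohort` standardizes within each cohort (each dataset gets
#' mean 0, SD 1); `pooled` uses the mean and SD of all samples together, a
#' sensitivity mode for checking that between-cohort score shifts do not
#' drive downstream results.
#'
#' @param scores A `score_set`.
#' @param mode `"per_cohort"` or `"pooled"`.
#' @return The `score_set` with `z_score` filled.
#' @export
normalize_scores <- function(scores, mode = c("per_cohort", "pooled")) {
  mode <- match.arg(mode)
  unit <- if (mode == "pooled") rep("pooled", nrow(scores)) else scores$cohort_id
  z <- numeric(nrow(scores))
  for (u in unique(unit)) {
    i <- unit == u
    if (sum(i) < 2L) stop(sprintf("normalization unit '%s' has fewer than 2 samples", u),
                          call. = FALSE)
    s <- sd(scores$raw_score[i])
    if (!is.finite(s) || s == 0) {
      stop(sprintf("normalization unit '%s' has zero score variance", u), call. = FALSE)
    }
    z[i] <- (scores$raw_score[i] - mean(scores$raw_score[i])) / s
  }
  scores$z_score <- z
  attr(scores, "normalization") <- mode
  scores
}
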