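#' Covariate-adjusted AUC for a binary outcome
#'
#' Fits the maximum-likelihood logistic regression
#' `outcome ~ score + age + sex` and computes the AUC of the fitted linear
#' predictor, with a 95% confidence interval by the DeLong method. This is
#' the "joint" adjustment convention (the ROC is taken on the combined
#' predictor); `adjustment = "residual"` instead residualizes the score on
#' age and sex by least squares and takes the ROC of the residualized score
#' alone.
#'
#' @param z Numeric score vector.
#' @param outcome Logical (or 0/1) outcome; both classes must be present.
#' @param age,sex Covariates (`sex` character/factor or 0/1).
#' @param adjustment `"joint"` or `"residual"`.
#' @return List of class `adjusted_auc`: `auc`, `ci_low`, `ci_high`,
#'   `n_case`, `n_control`, `adjustment`.
#' @export
adjusted_auc <- function(z, outcome, age, sex, adjustment = c("joint", "residual")) {
  adjustment <- match.arg(adjustment)
  outcome <- as.logical(outcome)
  if (length(unique(outcome)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  sexn <- if (is.numeric(sex)) sex else as.numeric(factor(sex))
  if (adjustment == "joint") {
    fit <- suppressWarnings(
      glm(outcome ~ z + age + sexn, family = binomial(), control = list(maxit = 100))
    )
    if (!fit$converged) stop("logistic fit did not converge (separation?)", call. = FALSE)
    predictor <- fit$linear.predictors
  } else {
    predictor <- residuals(lm(z ~ age + sexn))
  }
  roc <- pROC::roc(response = outcome, predictor = predictor,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(pROC::ci.auc(roc, method = "delong"))  # degenerate AUC=1 CI warns
  structure(list(auc = as.numeric(pROC::auc(roc)),
                 ci_low = ci[1], ci_high = ci[3],
                 n_case = sum(outcome), n_control = sum(!outcome),
                 adjustment = adjustment),
            class = "adjusted_auc")
}

#' @export
print.adjusted_auc <- function(x, ...) {
  cat(sprintf("AUC = %.4f [95%% CI %.4f-%.4f] (%s adjustment; %d cases / %d controls)\n",
              x$auc, x$ci_low, x$ci_high, x$adjustment, x$n_case, x$n_control))
  invisible(x)
}

#' Rank-based inverse-normal transformation
#'
#' `y_i = qnorm((rank_i - 3/8) / (n + 1/4))` with the Blom offset `c = 3/8`;
#' ties receive their average rank, so the transform is invariant to any
#' strictly monotone transformation of the input.
#'
#' @param x Numeric vector (`n >= 2`, not all equal).
#' @return The transformed vector.
#' @export
int_transform <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  if (length(unique(x[!is.na(x)])) < 2L) {
    stop("all values are equal: rank-based transform undefined", call. = FALSE)
  }
  r <- rank(x, ties.method = "average", na.last = "keep")
  n_obs <- sum(!is.na(x))
  qnorm((r - 3 / 8) / (n_obs + 1 / 4))
}

#' Covariate-adjusted Spearman correlation of a score with a trait
#'
#' The trait is inverse-normal transformed ([int_transform()]), residualized
#' by least squares on the covariates (age, age^2, sex and any extra columns,
#' e.g. principal components), and the Spearman rank correlation between the
#' residuals and the score is returned with the t-approximation p-value.
#'
#' @param z Numeric score vector.
#' @param trait Quantitative trait (e.g. BMI).
#' @param age,sex Optional covariates; age enters linearly and squared.
#' @param extra Optional numeric matrix/data.frame of further covariates.
#' @return List: `rho`, `p`, `n`.
#' @export
adjusted_spearman <- function(z, trait, age = NULL, sex = NULL, extra = NULL) {
  covs <- list()
  if (!is.null(age)) { covs$age <- age; covs$age2 <- age^2 }
  if (!is.null(sex)) covs$sex <- if (is.numeric(sex)) sex else as.numeric(factor(sex))
  if (!is.null(extra)) {
    extra <- as.data.frame(extra)
    covs <- c(covs, as.list(extra))
  }
  ok <- complete.cases(z, trait, if (length(covs)) as.data.frame(covs) else NULL)
  if (sum(ok) < 10L) stop("need >= 10 complete cases", call. = FALSE)
  y <- int_transform(trait[ok])
  if (length(covs)) {
    X <- cbind(1, as.matrix(as.data.frame(covs))[ok, , drop = FALSE])
    q <- qr(X)
    if (q$rank < ncol(X)) stop("covariate matrix is rank deficient", call. = FALSE)
    y <- y - X %*% qr.coef(q, y)
  }
  n <- sum(ok)
  rho <- cor(rank(y), rank(z[ok]))
  tstat <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(rho = rho, p = p, n = n)
}

#' Evaluate candidate models and select the best by adjusted AUC
#'
#' Scores the training panel with every candidate model, normalizes within
#' cohort, computes the covariate-adjusted AUC for the obesity outcome and
#' the adjusted Spearman correlation with BMI, and selects the model with the
#' highest AUC. Ties are broken by fewer model variants, then lexicographic
#' model id. Models that fail to score (e.g. empty grid points) are recorded
#' and skipped.
#'
#' @param models A `pgs_model_grid` or list of `pgs_model` objects.
#' @param panel Training `genotype_panel`.
#' @param pheno Matching `cohort_table`.
#' @param adjustment Passed to [adjusted_auc()].
#' @return List of class `model_selection`: `report` (one row per evaluated
#'   model: model_id, method, n_variants, auc, ci_low, ci_high, spearman_rho),
#'   `best_model_id`, `best_model`, `failed` (character vector of model ids
#'   that could not be evaluated).
#' @export
select_best <- function(models, panel, pheno, adjustment = c("joint", "residual")) {
  adjustment <- match.arg(adjustment)
  models <- grid_models(models)
  if (length(models) == 0L) stop("no scoreable model supplied", call. = FALSE)
  rows <- list()
  failed <- character(0)
  for (m in models) {
    res <- tryCatch({
      sc <- pgs_score(panel, m, cohort_id = pheno$cohort_id)
      sc <- normalize_scores(sc, "per_cohort")
      a <- adjusted_auc(sc$z_score, pheno$obesity, pheno$age, pheno$sex,
                        adjustment = adjustment)
      sp <- adjusted_spearman(sc$z_score, pheno$bmi, age = pheno$age, sex = pheno$sex)
      data.frame(model_id = m$model_id, method = m$method,
                 n_variants = nrow(m$weights),
                 auc = a$auc, ci_low = a$ci_low, ci_high = a$ci_high,
                 spearman_rho = sp$rho, stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) failed <- c(failed, m$model_id) else rows[[m$model_id]] <- res
  }
  if (length(rows) == 0L) stop("every candidate model failed scoring", call. = FALSE)
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  ord <- order(-report$auc, report$n_variants, report$model_id)
  best_id <- report$model_id[ord[1]]
  best <- models[[which(vapply(models, `[[`, character(1), "model_id") == best_id)]]
  structure(list(report = report, best_model_id = best_id, best_model = best,
                 failed = failed),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> %d models evaluated; best: %s (AUC %.4f)\n",
              nrow(x$report), x$best_model_id,
              x$report$auc[x$report$model_id == x$best_model_id]))
  invisible(x)
}
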