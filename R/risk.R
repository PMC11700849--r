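#' Percentile-based genetic risk groups
#'
#' Ranks scores ascending (ties broken by stable input order), assigns
#' percentile bin `ceil(100 * rank / n)` and the risk category: low =
#' percentiles 1-10, intermediate = 11-90, high = 91-100. The assignment is
#' invariant under any strictly monotone transform of the scores.
#'
#' @param z Numeric scores (`n >= 10`; `n >= 100` recommended so every bin is
#'   populated).
#' @return A data.frame of class `risk_groups`: `percentile` (1-100) and
#'   `category` (factor low/intermediate/high), one row per input score.
#' @examples
#' g <- assign_percentiles(rnorm(200))
#' table(g$category)
#' @export
assign_percentiles <- function(z) {
  n <- length(z)
  if (n < 10L) stop("need at least 10 scores", call. = FALSE)
  r <- rank(z, ties.method = "first")
  bin <- as.integer(ceiling(100 * r / n))
  category <- cut(bin, breaks = c(0, 10, 90, 100),
                  labels = c("low", "intermediate", "high"))
  out <- data.frame(percentile = bin, category = category)
  class(out) <- c("risk_groups", "data.frame")
  out
}

#' Obesity prevalence by PGS percentile, baseline-subtracted
#'
#' Prevalence per percentile bin is the mean outcome among individuals in the
#' bin; the elevation subtracts the prevalence of the 1st (lowest) percentile
#' from every bin, so the curve starts at exactly zero and is comparable
#' across cohorts with different baseline prevalences. Empty bins are
#' recorded as missing, not zero.
#'
#' @param groups A `risk_groups` from [assign_percentiles()].
#' @param outcome Logical (or 0/1) outcome aligned with `groups`.
#' @return A data.frame of class `prevalence_curve`: `percentile` (1-100),
#'   `n`, `prevalence`, `elevation`.
#' @export
prevalence_curve <- function(groups, outcome) {
  stopifnot(nrow(groups) == length(outcome))
  outcome <- as.numeric(outcome)
  bins <- seq_len(100)
  n <- vapply(bins, function(b) sum(groups$percentile == b), numeric(1))
  prev <- vapply(bins, function(b) {
    i <- groups$percentile == b
    if (!any(i)) NA_real_ else mean(outcome[i])
  }, numeric(1))
  elev <- prev - prev[1]
  out <- data.frame(percentile = bins, n = as.integer(n),
                    prevalence = prev, elevation = elev)
  class(out) <- c("prevalence_curve", "data.frame")
  out
}

wald_or_rows <- function(fit, terms, labels, n) {
  sm <- summary(fit)$coefficients
  rows <- lapply(seq_along(terms), function(i) {
    b <- sm[terms[i], "Estimate"]
    se <- sm[terms[i], "Std. Error"]
    data.frame(
      comparison = labels[i],
      log_or = b, se = se, or = exp(b),
      ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
      p = sm[terms[i], "Pr(>|z|)"], n = n,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

fit_logistic <- function(formula, data) {
  fit <- suppressWarnings(
    glm(formula, data = data, family = binomial(), control = list(maxit = 100))
  )
  if (!fit$converged) stop("logistic fit did not converge (separation?)", call. = FALSE)
  fit
}

#' Odds ratios for genetic risk categories
#'
#' Logistic regression `outcome ~ intermediate + high + age + sex` with the
#' low genetic risk group as reference; Wald 95% CIs (`exp(logOR +/- 1.96
#' SE)`) and p-values per category coefficient.
#'
#' @param outcome Logical (or 0/1) outcome.
#' @param groups A `risk_groups` aligned with `outcome`.
#' @param age,sex Covariates.
#' @return Data.frame of class `or_result`: one row per comparison
#'   (`intermediate_vs_low`, `high_vs_low`) with log_or, se, or, ci_low,
#'   ci_high, p, n.
#' @export
category_or <- function(outcome, groups, age, sex) {
  if (any(table(groups$category) == 0)) {
    stop("every risk category must be nonempty", call. = FALSE)
  }
  dat <- data.frame(
    y = as.logical(outcome),
    intermediate = as.numeric(groups$category == "intermediate"),
    high = as.numeric(groups$category == "high"),
    age = age,
    sex = if (is.numeric(sex)) sex else as.numeric(factor(sex))
  )
  fit <- fit_logistic(y ~ intermediate + high + age + sex, dat)
  out <- wald_or_rows(fit, c("intermediate", "high"),
                      c("intermediate_vs_low", "high_vs_low"), nrow(dat))
  class(out) <- c("or_result", "data.frame")
  out
}

#' Quintile assignment for a lifestyle exposure
#'
#' Boundaries at the empirical 20/40/60/80 percentiles using the same rank
#' convention as [assign_percentiles()] (`ceil(5 * rank / n)`, ties broken by
#' stable input order). Missing exposures are excluded (label `NA`) and
#' counted in the `n_missing` attribute. A warning reports realized group
#' sizes when a value occurring in more than 20% of the data spans a quintile
#' boundary.
#'
#' @param x Numeric exposure values (>= 5 non-missing).
#' @return Integer vector of quintile labels 1-5 (NA where `x` is missing),
#'   with attribute `n_missing`.
#' @export
assign_quintiles <- function(x) {
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 5L) stop("need at least 5 non-missing values", call. = FALSE)
  q <- rep(NA_integer_, length(x))
  r <- rank(x[obs], ties.method = "first")
  q[obs] <- as.integer(ceiling(5 * r / n))
  tab <- table(x[obs])
  big <- as.numeric(names(tab)[tab / n > 0.2])
  if (length(big)) {
    spans <- vapply(big, function(v) {
      qs <- unique(q[obs][x[obs] == v])
      length(qs) > 1L
    }, logical(1))
    if (any(spans)) {
      warning(sprintf(
        "tied exposure value spans a quintile boundary; realized sizes: %s",
        paste(table(q[obs]), collapse = "/")))
    }
  }
  attr(q, "n_missing") <- sum(!obs)
  q
}

#' Quintile trend odds ratios within genetic risk strata
#'
#' Within each genetic risk category separately: (a) per-quintile ORs versus
#' Q1 by indicator coding, and (b) the trend OR per quintile increment from
#' `outcome ~ quintile_index + age + sex` with the quintile entered as a
#' single numeric 1-5 term. All fits are maximum-likelihood logistic
#' regressions with Wald CIs. Strata with fewer than 50 samples are still
#' fitted but flagged `low_n`.
#'
#' @param outcome Logical (or 0/1) outcome.
#' @param quintiles Integer 1-5 labels from [assign_quintiles()] (NA rows are
#'   dropped).
#' @param groups A `risk_groups` aligned with `outcome`.
#' @param age,sex Covariates.
#' @return Data.frame of class `trend_result`: one row per stratum and term
#'   (`Q1` reference with OR 1, `Q2`..`Q5` vs Q1, and `trend`), with or,
#'   ci_low, ci_high, p, n, low_n.
#' @export
trend_or <- function(outcome, quintiles, groups, age, sex) {
  stopifnot(length(outcome) == nrow(groups), length(quintiles) == nrow(groups))
  sexn <- if (is.numeric(sex)) sex else as.numeric(factor(sex))
  rows <- list()
  for (cat in levels(groups$category)) {
    i <- which(groups$category == cat & !is.na(quintiles))
    n_i <- length(i)
    low_n <- n_i < 50L
    dat <- data.frame(y = as.logical(outcome[i]),
                      q = quintiles[i], age = age[i], sex = sexn[i])
    qref <- data.frame(comparison = "Q1", log_or = 0, se = NA_real_, or = 1,
                       ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                       n = n_i, stringsAsFactors = FALSE)
    fit_ind <- fit_logistic(y ~ factor(q, levels = 1:5) + age + sex, dat)
    terms <- sprintf("factor(q, levels = 1:5)%d", 2:5)
    present <- terms %in% rownames(summary(fit_ind)$coefficients)
    qrows <- wald_or_rows(fit_ind, terms[present],
                          sprintf("Q%d", 2:5)[present], n_i)
    fit_tr <- fit_logistic(y ~ q + age + sex, dat)
    trow <- wald_or_rows(fit_tr, "q", "trend", n_i)
    block <- rbind(qref, qrows, trow)
    block$stratum <- cat
    block$low_n <- low_n
    rows[[cat]] <- block
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[, c("stratum", "comparison", "log_or", "se", "or",
                 "ci_low", "ci_high", "p", "n", "low_n")]
  class(out) <- c("trend_result", "data.frame")
  out
}

#' Default spot-urine sodium coefficients
#'
#' Editable coefficient set for [estimate_sodium()]: the predicted 24-hour
#' creatinine excretion `PRCr24 = cr_age * age + cr_weight * weight +
#' cr_height * height + cr_intercept` (mg/day) and the power law
#' `Na24(mEq/day) = a * XNa^b` with `XNa = spot_Na / (spot_Cr * 10) * PRCr24`,
#' converted to grams/day with the sodium molar weight `mw` (g/mol).
#'
#' @return Named list of coefficients.
#' @export
tanaka_coefficients <- function() {
  list(a = 21.98, b = 0.392,
       cr_age = -2.04, cr_weight = 14.89, cr_height = 16.14,
       cr_intercept = -2244.45,
       mw = 22.99)
}

#' Estimate daily sodium intake from spot urine
#'
#' Applies the configured spot-urine formula (defaults:
#' [tanaka_coefficients()]) to estimate 24-hour sodium excretion in grams per
#' day. Output is monotone increasing in the spot sodium concentration when
#' the other fields are held fixed.
#'
#' @param spot_na Spot urine sodium concentration (mEq/L), positive.
#' @param spot_cr Spot urine creatinine (mg/dL), strictly positive.
#' @param age Age in years.
#' @param weight Body weight in kg.
#' @param height Height in cm.
#' @param coeffs Coefficient list as in [tanaka_coefficients()].
#' @return Estimated sodium intake in g/day.
#' @export
estimate_sodium <- function(spot_na, spot_cr, age, weight, height,
                            coeffs = tanaka_coefficients()) {
  if (any(spot_cr <= 0)) stop("spot creatinine must be positive", call. = FALSE)
  if (any(spot_na <= 0)) stop("spot sodium must be positive", call. = FALSE)
  pr_cr24 <- coeffs$cr_age * age + coeffs$cr_weight * weight +
    coeffs$cr_height * height + coeffs$cr_intercept
  x_na <- spot_na / (spot_cr * 10) * pr_cr24
  na24_meq <- coeffs$a * x_na^coeffs$b
  na24_meq * coeffs$mw / 1000
}
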