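#' Quality-control thresholds
#'
#' Sample and variant filters with defaults matching standard imputed-array
#' QC: call rate < 0.95 (samples and variants), exact Hardy-Weinberg p <
#' 1e-6, minor allele frequency < 0.01, and imputation R^2 < 0.3 are removed.
#' All comparisons are strict, so boundary values survive.
#'
#' @param sample_call_rate_min,variant_call_rate_min Minimum call rates.
#' @param hwe_p_min Minimum exact HWE p-value.
#' @param maf_min Minimum minor allele frequency.
#' @param imputation_r2_min Minimum imputation quality R^2.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_call_rate_min = 0.95,
                          variant_call_rate_min = 0.95,
                          hwe_p_min = 1e-6,
                          maf_min = 0.01,
                          imputation_r2_min = 0.3) {
  th <- list(
    sample_call_rate_min = sample_call_rate_min,
    variant_call_rate_min = variant_call_rate_min,
    hwe_p_min = hwe_p_min,
    maf_min = maf_min,
    imputation_r2_min = imputation_r2_min
  )
  stopifnot(all(unlist(th) > 0), all(unlist(th) <= 1))
  structure(th, class = "qc_thresholds")
}

new_qc_report <- function(stage, filters, n_input, n_surviving, dims) {
  structure(list(stage = stage, filters = filters, n_input = n_input,
                 n_surviving = n_surviving, dims = dims),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report: %s> %d -> %d\n", x$stage, x$n_input, x$n_surviving))
  print(x$filters, row.names = FALSE)
  invisible(x)
}

#' Sample-level quality control
#'
#' Removes samples with call rate below threshold, then failed-ancestry flags,
#' then sex-mismatch flags, in that order; a sample failing several filters is
#' counted once under the first. Call rate is the fraction of non-missing
#' dosages.
#'
#' @param panel A `genotype_panel`.
#' @param th A [qc_thresholds()].
#' @return List with elements `panel` (filtered) and `report` (`qc_report`).
#' @export
sample_qc <- function(panel, th = qc_thresholds()) {
  cr <- rowMeans(!is.na(panel$dosages))
  fail_cr <- cr < th$sample_call_rate_min
  fail_anc <- !fail_cr & !panel$samples$ancestry_ok
  fail_sex <- !fail_cr & !fail_anc & !panel$samples$sex_consistent
  keep <- !(fail_cr | fail_anc | fail_sex)
  if (!any(keep)) stop("sample QC removed every sample", call. = FALSE)
  filters <- data.frame(
    filter = c("call_rate", "ancestry", "sex_mismatch"),
    n_removed = c(sum(fail_cr), sum(fail_anc), sum(fail_sex)),
    stringsAsFactors = FALSE
  )
  out <- new_genotype_panel(
    panel$dosages[keep, , drop = FALSE],
    panel$variants,
    panel$samples[keep, , drop = FALSE]
  )
  report <- new_qc_report("samples", filters, nrow(panel$samples), sum(keep),
                          dim(out$dosages))
  list(panel = out, report = report)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test with the probability-ordering convention:
#' given the observed allele counts, the p-value is the sum of probabilities of
#' all heterozygote counts whose conditional probability does not exceed that
#' of the observed configuration. Probabilities are evaluated by the standard
#' recurrence over heterozygote counts, accumulated in log space.
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts (total >= 1).
#' @return The exact p-value in `(0, 1]`; monomorphic input returns 1.
#' @examples
#' hwe_exact_p(50, 0, 50)   # maximal heterozygote deficit: tiny p
#' hwe_exact_p(25, 50, 25)  # perfect HWE proportions: p = 1
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be >= 1", call. = FALSE)
  n_A <- 2 * n_AA + n_Aa
  n_a <- 2 * n_aa + n_Aa
  rare <- min(n_A, n_a)
  if (rare == 0) return(1)

  # heterozygote counts share the parity of the rare allele count
  h_min <- rare %% 2L
  h_vals <- seq.int(h_min, rare, by = 2L)

  # unnormalized probabilities by recurrence:
  # P(h+2)/P(h) = 4 * nAA(h) * naa(h) / ((h+2) * (h+1))
  # with nAA(h) = (n_A - h)/2, naa(h) = (n_a - h)/2; accumulated in log space
  # for stability at large totals
  k <- length(h_vals)
  logp <- numeric(k)
  if (k > 1) {
    ratio <- function(h) {
      log(4) + log((n_A - h) / 2) + log((n_a - h) / 2) - log(h + 2) - log(h + 1)
    }
    for (i in 2:k) logp[i] <- logp[i - 1L] + ratio(h_vals[i - 1L])
  }
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))

  obs <- match(n_Aa, h_vals)
  if (is.na(obs)) stop("observed heterozygote count inconsistent with allele totals",
                       call. = FALSE)
  p <- sum(prob[prob <= prob[obs] * (1 + 1e-10)])
  min(p, 1)
}

hard_call <- function(dosages) {
  g <- round(dosages)
  g[g < 0] <- 0
  g[g > 2] <- 2
  g
}

#' Variant-level quality control
#'
#' Removes variants failing, in order: call rate, exact Hardy-Weinberg test on
#' hard-called genotypes (dosages rounded to the nearest integer), minor
#' allele frequency (computed from observed dosages as mean/2, folded to
#' <= 0.5), and imputation R^2. A variant failing several filters is counted
#' once under the first. All comparisons are strict inequalities, so boundary
#' values (e.g. R^2 exactly 0.3) survive. Apply [sample_qc()] first.
#'
#' @inheritParams sample_qc
#' @return List with elements `panel` (filtered) and `report` (`qc_report`).
#' @export
variant_qc <- function(panel, th = qc_thresholds()) {
  x <- panel$dosages
  n <- nrow(x)
  cr <- colMeans(!is.na(x))
  fail_cr <- cr < th$variant_call_rate_min

  g <- hard_call(x)
  n0 <- colSums(g == 0, na.rm = TRUE)
  n1 <- colSums(g == 1, na.rm = TRUE)
  n2 <- colSums(g == 2, na.rm = TRUE)
  hwe_p <- vapply(seq_len(ncol(x)), function(j) hwe_exact_p(n2[j], n1[j], n0[j]),
                  numeric(1))
  fail_hwe <- !fail_cr & (hwe_p < th$hwe_p_min)

  af <- colMeans(x, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  fail_maf <- !fail_cr & !fail_hwe & (maf < th$maf_min)

  fail_r2 <- !fail_cr & !fail_hwe & !fail_maf &
    (panel$variants$imputation_r2 < th$imputation_r2_min)

  keep <- !(fail_cr | fail_hwe | fail_maf | fail_r2)
  if (!any(keep)) stop("variant QC removed every variant", call. = FALSE)
  filters <- data.frame(
    filter = c("call_rate", "hwe", "maf", "imputation_r2"),
    n_removed = c(sum(fail_cr), sum(fail_hwe), sum(fail_maf), sum(fail_r2)),
    stringsAsFactors = FALSE
  )
  out <- new_genotype_panel(
    x[, keep, drop = FALSE],
    panel$variants[keep, , drop = FALSE],
    panel$samples
  )
  report <- new_qc_report("variants", filters, ncol(x), sum(keep), dim(out$dosages))
  report$removed_ids <- panel$variants$id[!keep]
  list(panel = out, report = report)
}
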