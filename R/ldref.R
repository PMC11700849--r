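#' Windowed LD reference from a genotype panel
#'
#' Computes pairwise dosage correlations within fixed-size, non-overlapping
#' windows of variants taken in (chromosome, position) order. Windows
#' partition the variant list and approximate long-range LD handling: LD is
#' assumed zero across windows, which matches the block-diagonal structure of
#' the synthetic panels and is the working assumption of the shrinkage stage.
#'
#' @param panel A `genotype_panel` (typically the target or a reference
#'   cohort after QC).
#' @param window_size Number of variants per window (last window may be
#'   smaller).
#' @return An `ld_reference`: list with `variants` (metadata in window
#'   order), `window` (integer window index per variant) and `R` (list of
#'   per-window correlation matrices, diagonal 1). Correlations involving a
#'   constant variant are set to 0.
#' @export
ld_reference <- function(panel, window_size = 200L) {
  stopifnot(window_size >= 1L)
  ord <- order(panel$variants$chromosome, panel$variants$position)
  variants <- panel$variants[ord, , drop = FALSE]
  x <- panel$dosages[, ord, drop = FALSE]
  m <- ncol(x)
  window <- ceiling(seq_len(m) / window_size)
  R <- lapply(split(seq_len(m), window), function(idx) {
    r <- suppressWarnings(stats::cor(x[, idx, drop = FALSE],
                                     use = "pairwise.complete.obs"))
    r[is.na(r)] <- 0
    diag(r) <- 1
    unname(r)
  })
  window_start <- vapply(split(seq_len(m), window), min, numeric(1))
  structure(list(variants = variants, window = as.integer(window), R = R,
                 window_size = as.integer(window_size),
                 window_start = window_start),
            class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("<ld_reference> %d variants in %d windows (max size %d)\n",
              nrow(x$variants), length(x$R), max(table(x$window))))
  invisible(x)
}

# Align summary stats to the LD reference order; returns aligned data.frame
# restricted to the shared variant universe, with NA-beta variants dropped.
align_sumstats <- function(ss, ld) {
  idx <- match(ld$variants$id, ss$id)
  keep <- !is.na(idx)
  if (!any(keep)) stop("summary statistics share no variants with the LD reference",
                       call. = FALSE)
  out <- ss[idx[keep], , drop = FALSE]
  out$ld_index <- which(keep)
  ok <- !is.na(out$beta_marginal)
  out[ok, , drop = FALSE]
}
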