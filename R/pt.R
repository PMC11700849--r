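#' LD clumping plus p-value thresholding (P+T)
#'
#' Greedy p-value-ordered clumping: repeatedly take the remaining variant with
#' the smallest p-value not exceeding `p_threshold`, select it, and remove all
#' unselected variants in its LD window whose squared correlation with it
#' exceeds `r2_threshold`. Selected variants carry their marginal effect as
#' the PGS weight on the stated effect allele. Ties in p are broken by
#' (chromosome, position), so the selected set does not depend on input row
#' order.
#'
#' @param ss A `summary_stats` data.frame (see [simulate_gwas()] for columns).
#' @param ld An [ld_reference()] sharing a variant universe with `ss`.
#' @param p_threshold Keep only variants with `p <= p_threshold`.
#' @param r2_threshold Remove variants with `r^2 > r2_threshold` to a selected
#'   variant (strict inequality).
#' @param model_id Optional model identifier.
#' @return A `pgs_model` with method `"pt"`.
#' @export
clump_threshold <- function(ss, ld, p_threshold, r2_threshold,
                            model_id = sprintf("pt_p%g_r%g", p_threshold, r2_threshold)) {
  stopifnot(p_threshold > 0, p_threshold <= 1, r2_threshold >= 0)
  al <- align_sumstats(ss, ld)
  cand <- which(al$p_value <= p_threshold)
  if (length(cand) == 0L) {
    stop(empty_model_error(model_id,
         sprintf("no variant passes p <= %g", p_threshold)))
  }
  ord <- cand[order(al$p_value[cand], al$chromosome[cand], al$position[cand])]

  # status: 0 free, 1 selected, 2 removed by LD with a selected variant
  status <- integer(nrow(al))
  win <- ld$window[al$ld_index]
  # position inside the window's correlation matrix (windows are contiguous
  # ranges of the LD reference order)
  local <- al$ld_index - ld$window_start[as.character(win)] + 1L
  win_members <- split(seq_len(nrow(al)), win)

  for (i in ord) {
    if (status[i] != 0L) next
    status[i] <- 1L
    R <- ld$R[[as.character(win[i])]]
    members <- win_members[[as.character(win[i])]]
    r2 <- R[local[members], local[i]]^2
    prune <- members[status[members] == 0L & r2 > r2_threshold & members != i]
    status[prune] <- 2L
  }
  sel <- which(status == 1L)
  sel <- sel[order(al$chromosome[sel], al$position[sel])]
  new_pgs_model(model_id, "pt",
                list(p_threshold = p_threshold, r2_threshold = r2_threshold),
                weights_frame(al[sel, , drop = FALSE], al$beta_marginal[sel]))
}

#' Build the full P+T model grid
#'
#' One candidate model per combination of p-value threshold and r^2 threshold.
#' The default grids (six p-value thresholds by four r^2 thresholds) yield 24
#' models. Grid points where no variant passes the p-value threshold are
#' retained as explicit failure entries rather than silently dropped.
#'
#' @inheritParams clump_threshold
#' @param p_thresholds Numeric vector of p-value thresholds.
#' @param r2_thresholds Numeric vector of r^2 thresholds.
#' @return A list of class `pgs_model_grid`: each element is either a
#'   `pgs_model` or a failure record (list with `model_id`, `method`,
#'   `hyperparams`, `error`). Length equals the grid size.
#' @export
build_pt_grid <- function(ss, ld,
                          p_thresholds = c(1, 5e-1, 5e-2, 5e-4, 5e-6, 5e-8),
                          r2_thresholds = c(0.2, 0.4, 0.6, 0.8)) {
  grid <- expand.grid(p_threshold = p_thresholds, r2_threshold = r2_thresholds,
                      KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- grid$p_threshold[i]; r2 <- grid$r2_threshold[i]
    id <- sprintf("pt_p%g_r%g", p, r2)
    out[[i]] <- tryCatch(
      clump_threshold(ss, ld, p, r2, model_id = id),
      pgstrat_empty_model = function(e) {
        list(model_id = id, method = "pt",
             hyperparams = list(p_threshold = p, r2_threshold = r2),
             error = conditionMessage(e))
      }
    )
  }
  names(out) <- vapply(out, `[[`, character(1), "model_id")
  structure(out, class = "pgs_model_grid")
}

#' @export
print.pgs_model_grid <- function(x, ...) {
  ok <- vapply(x, inherits, logical(1), "pgs_model")
  cat(sprintf("<pgs_model_grid> %d grid points (%d models, %d failures)\n",
              length(x), sum(ok), sum(!ok)))
  invisible(x)
}

#' Successful models in a grid
#'
#' @param grid A `pgs_model_grid` (or plain list of models).
#' @return List of `pgs_model` objects, failures dropped.
#' @export
grid_models <- function(grid) {
  Filter(function(m) inherits(m, "pgs_model"), unclass(grid))
}
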