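new_pgs_model <- function(model_id, method, hyperparams, weights) {
  stopifnot(
    is.character(model_id), length(model_id) == 1L,
    method %in% c("pt", "ldpred_inf", "ldpred_grid"),
    is.data.frame(weights), nrow(weights) >= 1L,
    !anyDuplicated(weights$variant_id),
    all(is.finite(weights$weight))
  )
  structure(list(model_id = model_id, method = method,
                 hyperparams = hyperparams, weights = weights),
            class = "pgs_model")
}

#' @export
print.pgs_model <- function(x, ...) {
  hp <- paste(names(x$hyperparams),
              vapply(x$hyperparams, format, character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("<pgs_model %s> method=%s, %d variants (%s)\n",
              x$model_id, x$method, nrow(x$weights), hp))
  invisible(x)
}

empty_model_error <- function(model_id, msg) {
  structure(
    class = c("pgstrat_empty_model", "error", "condition"),
    list(message = sprintf("%s: %s", model_id, msg), call = NULL)
  )
}

weights_frame <- function(ss_aligned, weight) {
  data.frame(
    variant_id = ss_aligned$id,
    chromosome = ss_aligned$chromosome,
    position = ss_aligned$position,
    effect_allele = ss_aligned$effect_allele,
    other_allele = ss_aligned$other_allele,
    weight = weight,
    stringsAsFactors = FALSE
  )
}
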