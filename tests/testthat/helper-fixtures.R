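# Shared fixture builders. Everything is generated in code at test time.

small_cfg <- function(...) {
  args <- modifyList(
    list(n_variants = 60L, n_blocks = 6L, block_r = 0.6,
         maf_range = c(0.1, 0.5), rho_causal = 0.2, h2 = 0.3,
         n_gwas = 2000L, cohort_sizes = c(300L, 300L), seed = 11L),
    list(...)
  )
  do.call(sim_config, args)
}

# A tiny hand-specified panel for scoring tests: explicit dosages/alleles.
toy_panel <- function(dosages, effect_allele, other_allele) {
  m <- ncol(dosages)
  variants <- data.frame(
    id = sprintf("rs%d", seq_len(m)),
    chromosome = 1L, position = seq_len(m) * 1000L,
    effect_allele = effect_allele, other_allele = other_allele,
    maf = pmin(colMeans(dosages, na.rm = TRUE) / 2,
               1 - colMeans(dosages, na.rm = TRUE) / 2),
    imputation_r2 = 1, stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = sprintf("s%d", seq_len(nrow(dosages))),
    ancestry_ok = TRUE, sex_consistent = TRUE, stringsAsFactors = FALSE
  )
  dimnames(dosages) <- list(samples$sample_id, variants$id)
  pgstrat:::new_genotype_panel(dosages, variants, samples)
}

toy_model <- function(weights, effect_allele, other_allele,
                      ids = sprintf("rs%d", seq_along(weights))) {
  pgstrat:::new_pgs_model(
    "toy", "pt", list(p_threshold = 1, r2_threshold = 1),
    data.frame(variant_id = ids, chromosome = 1L,
               position = seq_along(weights) * 1000L,
               effect_allele = effect_allele, other_allele = other_allele,
               weight = weights, stringsAsFactors = FALSE)
  )
}

# Small summary-stats table with hand-set p-values/betas over a given panel.
toy_sumstats <- function(panel, beta, se, p) {
  v <- panel$variants
  out <- data.frame(
    id = v$id, chromosome = v$chromosome, position = v$position,
    effect_allele = v$effect_allele, other_allele = v$other_allele,
    beta_marginal = beta, se = se, p_value = p,
    n = 1000L, imputation_r2 = v$imputation_r2, stringsAsFactors = FALSE
  )
  class(out) <- c("summary_stats", "data.frame")
  out
}
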