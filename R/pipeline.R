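default_pipeline_config <- function() {
  list(
    seed = 42L,
    simulation = list(
      n_variants = 2000L, n_blocks = 20L, block_r = 0.7,
      maf_range = c(0.05, 0.5), rho_causal = 0.03, h2 = 0.3,
      n_gwas = 20000L, training_n = 3000L,
      cohort_sizes = c(2000L, 2000L, 2000L),
      age_range = c(40, 80), sex_ratio = 0.65,
      lifestyle_effects = list(lte = -0.12, dla = 0, sodium = 0.12),
      heterogeneity_tau = 0, obesity_threshold = 25,
      bmi_mean = 23.2, bmi_sd = 3.6,
      missing_rate = 0, n_hwe_violators = 0L, n_low_r2 = 0L
    ),
    qc = list(
      sample_call_rate_min = 0.95, variant_call_rate_min = 0.95,
      hwe_p_min = 1e-6, maf_min = 0.01, imputation_r2_min = 0.3
    ),
    pgs = list(
      window_size = 200L,
      p_thresholds = c(1, 5e-1, 5e-2, 5e-4, 5e-6, 5e-8),
      r2_thresholds = c(0.2, 0.4, 0.6, 0.8),
      rho_grid = c(1, 0.3, 0.1, 0.03, 0.01, 0.003, 0.001),
      h2 = 0.3, n_iter = 600L, burnin = 100L
    ),
    scoring = list(normalization = "per_cohort", auc_adjustment = "joint"),
    stratify = list(sex_stratified = FALSE),
    meta = list(het_alpha = 0.05),
    power = list(
      n_per_study = c(50195, 11947, 6796), prevalence = 0.3,
      or_grid = seq(1.01, 1.08, by = 0.01),
      i2_grid = c(0, 0.2, 0.4, 0.6, 0.8),
      alpha = 0.05, n_sim = 500L
    )
  )
}

check_unknown_keys <- function(user, defaults, path = "") {
  bad <- character(0)
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      bad <- c(bad, full)
    } else if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
               is.list(user[[key]])) {
      bad <- c(bad, check_unknown_keys(user[[key]], defaults[[key]], full))
    }
  }
  bad
}

merge_config <- function(defaults, user) {
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]]) && !is.null(names(user[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]])
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or accepts a named list), rejects unknown keys, fills
#' every missing key from the documented defaults, and checks value ranges by
#' constructing the underlying [sim_config()] and [qc_thresholds()] objects.
#'
#' @param config Path to a YAML file, or a named list, or `NULL` for pure
#'   defaults.
#' @return A validated `pipeline_config` (named list).
#' @export
validate_config <- function(config = NULL) {
  defaults <- default_pipeline_config()
  user <- list()
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    user <- yaml::read_yaml(config)
  } else if (is.list(config)) {
    user <- config
  } else if (!is.null(config)) {
    stop("config must be a file path, a named list, or NULL", call. = FALSE)
  }
  if (length(user)) {
    bad <- check_unknown_keys(user, defaults)
    if (length(bad)) {
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  cfg <- merge_config(defaults, user)
  cfg$seed <- as.integer(cfg$seed)
  # range checks via the typed constructors
  as_sim_config(cfg)
  do.call(qc_thresholds, cfg$qc)
  stopifnot(cfg$scoring$normalization %in% c("per_cohort", "pooled"),
            cfg$scoring$auc_adjustment %in% c("joint", "residual"))
  structure(cfg, class = "pipeline_config")
}

as_sim_config <- function(cfg) {
  s <- cfg$simulation
  sim_config(
    n_variants = s$n_variants, n_blocks = s$n_blocks, block_r = s$block_r,
    maf_range = unlist(s$maf_range), rho_causal = s$rho_causal, h2 = s$h2,
    n_gwas = s$n_gwas, cohort_sizes = unlist(s$cohort_sizes),
    age_range = unlist(s$age_range), sex_ratio = s$sex_ratio,
    lifestyle_effects = unlist(s$lifestyle_effects),
    heterogeneity_tau = s$heterogeneity_tau,
    obesity_threshold = s$obesity_threshold,
    bmi_mean = s$bmi_mean, bmi_sd = s$bmi_sd,
    seed = cfg$seed
  )
}

stage_seed <- function(seed, stage) {
  (as.integer(seed) + 97L * as.integer(stage)) %% 2147483647L
}

write_stage_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  path
}

#' Run the full PGS stratification pipeline
#'
#' Executes the flowchart end to end: simulate a discovery GWAS sample and
#' summary statistics; simulate one training cohort and the configured
#' validation cohorts; run sample and variant QC; build an LD reference from
#' the training panel; construct the P+T and point-normal model grids; select
#' the best model by covariate-adjusted AUC on the training cohort; score and
#' normalize the validation cohorts; stratify into percentile risk groups and
#' compute prevalence curves, category ORs and lifestyle quintile trend ORs
#' per cohort; pool per-cohort estimates by meta-analysis; and run the power
#' simulation. Every stage output is written as a tidy TSV and a manifest of
#' checksums is produced. Per-stage seeds are derived deterministically from
#' the global seed (`seed + 97 * stage_index`), so individual stages can be
#' reproduced in isolation.
#'
#' @param config A path, list or `pipeline_config` (see [validate_config()]).
#' @param out_dir Output directory (created if missing).
#' @param seed Optional override of the config seed.
#' @return A list of class `run_manifest`: `config_hash`, `files` (data.frame
#'   of file names, md5 checksums, sizes), `results` (in-memory stage
#'   outputs), `timestamp`.
#' @export
run_all <- function(config = NULL, out_dir = tempfile("pgstrat_run_"),
                    seed = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (length(cfg$simulation$cohort_sizes) < 1L) {
    stop("validation stage requires at least one validation cohort", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- as_sim_config(cfg)
  th <- do.call(qc_thresholds, cfg$qc)
  files <- character(0)

  # effective config echo
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  files <- c(files, cfg_path)

  message("stage 1/8: simulating discovery GWAS and cohorts")
  effects <- simulate_effects(scfg, stage_seed(cfg$seed, 1L))
  gwas_panel <- simulate_panel(scfg, scfg$n_gwas, stage_seed(cfg$seed, 2L),
                               id_prefix = "G")
  gwas_pheno <- simulate_phenotypes(gwas_panel, effects, scfg, "gwas",
                                    stage_seed(cfg$seed, 3L))
  ss <- simulate_gwas(gwas_panel, gwas_pheno)
  files <- c(files, write_stage_tsv(ss, out_dir, "sumstats.tsv"))
  rm(gwas_panel, gwas_pheno)

  train_panel <- simulate_panel(scfg, cfg$simulation$training_n,
                                stage_seed(cfg$seed, 4L), id_prefix = "T")
  train_pheno <- simulate_phenotypes(train_panel, effects, scfg, "training",
                                     stage_seed(cfg$seed, 5L))
  val <- list()
  for (i in seq_along(scfg$cohort_sizes)) {
    pid <- sprintf("V%d", i)
    pan <- simulate_panel(scfg, scfg$cohort_sizes[i],
                          stage_seed(cfg$seed, 10L + i), id_prefix = pid)
    if (cfg$simulation$missing_rate > 0 || cfg$simulation$n_hwe_violators > 0 ||
        cfg$simulation$n_low_r2 > 0) {
      pan <- corrupt_panel(pan, cfg$simulation$missing_rate,
                           cfg$simulation$n_hwe_violators,
                           cfg$simulation$n_low_r2,
                           stage_seed(cfg$seed, 20L + i))
    }
    phe <- simulate_phenotypes(pan, effects, scfg, sprintf("cohort%d", i),
                               stage_seed(cfg$seed, 30L + i))
    val[[i]] <- list(panel = pan, pheno = phe)
  }
  # GWAS ids are prefixed distinctly; assert disjointness anyway
  stopifnot(!any(grepl("^G", c(train_panel$samples$sample_id,
                               unlist(lapply(val, function(v) v$panel$samples$sample_id))))))

  message("stage 2/8: quality control")
  qc_rows <- list()
  run_qc <- function(pan, label) {
    sq <- sample_qc(pan, th)
    vq <- variant_qc(sq$panel, th)
    qc_rows[[label]] <<- data.frame(
      dataset = label,
      stage = c(rep("samples", 3), rep("variants", 4)),
      filter = c(sq$report$filters$filter, vq$report$filters$filter),
      n_removed = c(sq$report$filters$n_removed, vq$report$filters$n_removed),
      stringsAsFactors = FALSE
    )
    vq$panel
  }
  train_panel <- run_qc(train_panel, "training")
  for (i in seq_along(val)) {
    val[[i]]$panel <- run_qc(val[[i]]$panel, sprintf("cohort%d", i))
  }
  files <- c(files, write_stage_tsv(do.call(rbind, qc_rows), out_dir, "qc_report.tsv"))

  message("stage 3/8: LD reference and model grids")
  ld <- ld_reference(train_panel, cfg$pgs$window_size)
  pt_grid <- build_pt_grid(ss, ld, cfg$pgs$p_thresholds, cfg$pgs$r2_thresholds)
  ld_grid <- build_ldpred_grid(ss, ld, h2 = cfg$pgs$h2, n = scfg$n_gwas,
                               rho_grid = cfg$pgs$rho_grid,
                               n_iter = cfg$pgs$n_iter, burnin = cfg$pgs$burnin,
                               seed = stage_seed(cfg$seed, 40L))
  all_models <- c(unclass(pt_grid), unclass(ld_grid))

  message("stage 4/8: model selection on the training cohort")
  sel <- select_best(all_models, train_panel, train_pheno,
                     adjustment = cfg$scoring$auc_adjustment)
  files <- c(files, write_stage_tsv(sel$report, out_dir, "model_selection.tsv"))
  best_path <- file.path(out_dir, "best_model.txt")
  write_pgs_model(sel$best_model, best_path)
  files <- c(files, best_path)

  message("stage 5/8: scoring and normalizing validation cohorts")
  score_list <- lapply(val, function(v)
    pgs_score(v$panel, sel$best_model, cohort_id = v$pheno$cohort_id))
  scores <- do.call(rbind, score_list)
  class(scores) <- c("score_set", "data.frame")
  scores <- normalize_scores(scores, cfg$scoring$normalization)
  files <- c(files, write_stage_tsv(scores, out_dir, "scores.tsv"))
  pheno_all <- do.call(rbind, lapply(val, `[[`, "pheno"))
  files <- c(files, write_stage_tsv(pheno_all, out_dir, "phenotypes.tsv"))
  kw <- kruskal.test(scores$z_score, factor(scores$cohort_id))

  message("stage 6/8: risk stratification")
  strat <- stratify_cohorts(scores, pheno_all,
                            sex_stratified = cfg$stratify$sex_stratified)
  files <- c(files, write_stage_tsv(strat$curves, out_dir, "prevalence_curves.tsv"))
  files <- c(files, write_stage_tsv(strat$category_ors, out_dir, "category_or.tsv"))
  files <- c(files, write_stage_tsv(strat$trend_ors, out_dir, "trend_or.tsv"))

  message("stage 7/8: meta-analysis")
  meta_cat <- meta_by(strat$category_ors, c("comparison", "subset"),
                      cfg$meta$het_alpha)
  meta_trend <- meta_by(strat$trend_ors[strat$trend_ors$comparison == "trend", ],
                        c("exposure", "stratum", "subset"), cfg$meta$het_alpha)
  files <- c(files, write_stage_tsv(meta_cat, out_dir, "meta_category.tsv"))
  files <- c(files, write_stage_tsv(meta_trend, out_dir, "meta_trend.tsv"))

  message("stage 8/8: power simulation")
  pw <- power_simulation(
    n_per_study = unlist(cfg$power$n_per_study),
    prevalence = cfg$power$prevalence,
    or_grid = unlist(cfg$power$or_grid),
    i2_grid = unlist(cfg$power$i2_grid),
    alpha = cfg$power$alpha, n_sim = cfg$power$n_sim,
    seed = stage_seed(cfg$seed, 50L)
  )
  files <- c(files, write_stage_tsv(pw, out_dir, "power_grid.tsv"))

  md5 <- tools::md5sum(files)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    files = data.frame(file = basename(files), md5 = unname(md5),
                       bytes = unname(file.size(files)), stringsAsFactors = FALSE),
    results = list(selection = sel, scores = scores, pheno = pheno_all,
                   stratification = strat, meta_category = meta_cat,
                   meta_trend = meta_trend, power = pw,
                   kruskal_wallis_p = kw$p.value,
                   pt_grid_size = length(pt_grid),
                   ldpred_grid_size = length(ld_grid)),
    timestamp = format(Sys.time(), tz = "UTC"),
    out_dir = out_dir
  )
  manifest_df <- manifest$files
  write_stage_tsv(manifest_df, out_dir, "manifest.tsv")
  structure(manifest, class = "run_manifest")
}

# Per-cohort stratification: percentiles, prevalence curves, category ORs and
# lifestyle quintile trend ORs (quintile cut-offs computed within cohort).
stratify_cohorts <- function(scores, pheno, sex_stratified = FALSE) {
  stopifnot(identical(scores$sample_id, pheno$sample_id))
  curves <- list(); cat_ors <- list(); trend_ors <- list()
  subsets <- if (sex_stratified) c("female", "male") else "all"
  for (sx in subsets) {
    for (cid in unique(scores$cohort_id)) {
      i <- scores$cohort_id == cid & (sx == "all" | pheno$sex == sx)
      z <- scores$z_score[i]; ph <- pheno[i, , drop = FALSE]
      groups <- assign_percentiles(z)
      cv <- prevalence_curve(groups, ph$obesity)
      cv$cohort_id <- cid; cv$subset <- sx
      curves[[paste(cid, sx)]] <- cv
      co <- category_or(ph$obesity, groups, ph$age, ph$sex)
      co$cohort_id <- cid; co$subset <- sx
      cat_ors[[paste(cid, sx)]] <- co
      for (expo in c("lte", "dla", "sodium")) {
        q <- assign_quintiles(ph[[expo]])
        tr <- trend_or(ph$obesity, q, groups, ph$age, ph$sex)
        tr$cohort_id <- cid; tr$exposure <- expo; tr$subset <- sx
        trend_ors[[paste(cid, expo, sx)]] <- tr
      }
    }
  }
  list(curves = do.call(rbind, curves),
       category_ors = do.call(rbind, cat_ors),
       trend_ors = do.call(rbind, trend_ors))
}

# Pool per-cohort log-ORs with auto_meta within each group defined by `by`.
meta_by <- function(or_table, by, het_alpha = 0.05) {
  or_table <- or_table[is.finite(or_table$log_or) & is.finite(or_table$se) &
                         !is.na(or_table$se), , drop = FALSE]
  keys <- unique(or_table[, by, drop = FALSE])
  rows <- list()
  for (r in seq_len(nrow(keys))) {
    sel <- rep(TRUE, nrow(or_table))
    for (b in by) sel <- sel & or_table[[b]] == keys[[b]][r]
    sub <- or_table[sel, , drop = FALSE]
    if (nrow(sub) < 2L) next
    res <- auto_meta(study_effects(sub$cohort_id, sub$log_or, sub$se, sub$n),
                     het_alpha = het_alpha)
    row <- keys[r, , drop = FALSE]
    row$model_used <- res$model_used
    row$or <- exp(res$estimate); row$ci_low <- exp(res$ci_low)
    row$ci_high <- exp(res$ci_high); row$p <- res$p
    row$Q <- res$Q; row$p_het <- res$p_het; row$i2 <- res$i2; row$tau2 <- res$tau2
    rows[[r]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d artifacts in %s (config %s)\n",
              nrow(x$files), x$out_dir, substr(x$config_hash, 1, 8)))
  invisible(x)
}
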