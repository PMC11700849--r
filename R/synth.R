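#' Simulation configuration for the synthetic multi-cohort generator
#'
#' Bundles every parameter of the synthetic data generator: the LD-blocked
#' genotype panel, the point-normal genetic architecture, the GWAS sample, the
#' validation cohort design, and the BMI liability model with lifestyle
#' covariates. Defaults describe the study conditions the package is calibrated
#' for: 2,000 variants in 20 AR(1) LD blocks, a causal fraction of 0.03, BMI
#' heritability 0.3, a 20,000-sample GWAS, and three validation cohorts of
#' 2,000 individuals each, with obesity defined as BMI >= 25 kg/m^2.
#'
#' @param n_variants Number of variants in the panel.
#' @param n_blocks Number of LD blocks; variants are split into contiguous
#'   blocks of near-equal size, independent across blocks.
#' @param block_r AR(1) correlation of the latent Gaussian within a block,
#'   in `[0, 1)`. Dosage-scale correlation is attenuated relative to this
#'   latent value (thresholding loses information).
#' @param maf_range Length-2 numeric in `(0, 0.5]`; per-variant minor allele
#'   frequencies are drawn uniformly from this interval.
#' @param rho_causal Fraction of causal variants in `(0, 1]` (the point-normal
#'   mixing weight, the "rho" of LDpred-style models).
#' @param h2 Fraction of trait variance explained by genetics, in `[0, 1)`.
#' @param n_gwas Sample size of the simulated discovery GWAS.
#' @param cohort_sizes Integer vector of validation cohort sizes (each >= 100).
#' @param age_range Length-2 numeric, years; ages are uniform on this range.
#' @param sex_ratio Fraction of females in each cohort.
#' @param lifestyle_effects Named numeric vector with elements `lte`, `dla`,
#'   `sodium`: liability-scale slopes per standard deviation of the covariate.
#'   Negative `lte` (leisure-time exercise is protective) and positive
#'   `sodium` match the directions the analysis is designed to detect.
#' @param heterogeneity_tau Between-cohort SD of the covariate slopes
#'   (0 = identical slopes in every cohort).
#' @param obesity_threshold BMI cut-off for the obesity flag (kg/m^2); the
#'   default 25 is the Japanese definition.
#' @param bmi_mean,bmi_sd Marginal mean and SD of simulated BMI (kg/m^2).
#' @param age_effect,sex_effect Liability-scale slopes for standardized age and
#'   for male sex.
#' @param gxe If `TRUE`, adds a gene-by-LTE interaction term on the liability
#'   scale (off by default: lifestyle is generated independent of genotype).
#' @param seed Default seed used by [run_all()] to derive per-stage seeds.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_variants = 200, n_blocks = 4, cohort_sizes = c(300, 300))
#' cfg$rho_causal
#' @export
sim_config <- function(n_variants = 2000L,
                       n_blocks = 20L,
                       block_r = 0.7,
                       maf_range = c(0.05, 0.5),
                       rho_causal = 0.03,
                       h2 = 0.3,
                       n_gwas = 20000L,
                       cohort_sizes = c(2000L, 2000L, 2000L),
                       age_range = c(40, 80),
                       sex_ratio = 0.65,
                       lifestyle_effects = c(lte = -0.12, dla = 0, sodium = 0.12),
                       heterogeneity_tau = 0,
                       obesity_threshold = 25,
                       bmi_mean = 23.2,
                       bmi_sd = 3.6,
                       age_effect = 0.1,
                       sex_effect = 0.15,
                       gxe = FALSE,
                       seed = 42L) {
  cfg <- list(
    n_variants = as.integer(n_variants), n_blocks = as.integer(n_blocks),
    block_r = block_r, maf_range = as.numeric(maf_range),
    rho_causal = rho_causal, h2 = h2, n_gwas = as.integer(n_gwas),
    cohort_sizes = as.integer(cohort_sizes), age_range = as.numeric(age_range),
    sex_ratio = sex_ratio,
    lifestyle_effects = lifestyle_effects,
    heterogeneity_tau = heterogeneity_tau,
    obesity_threshold = obesity_threshold,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    age_effect = age_effect, sex_effect = sex_effect,
    gxe = isTRUE(gxe), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_variants >= 1L, cfg$n_blocks >= 1L,
    cfg$n_variants >= cfg$n_blocks,
    cfg$block_r >= 0, cfg$block_r < 1,
    length(cfg$maf_range) == 2L,
    cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
    cfg$maf_range[1] <= cfg$maf_range[2],
    cfg$rho_causal > 0, cfg$rho_causal <= 1,
    cfg$h2 >= 0, cfg$h2 < 1,
    cfg$n_gwas >= 2L,
    cfg$sex_ratio >= 0, cfg$sex_ratio <= 1,
    cfg$heterogeneity_tau >= 0,
    all(c("lte", "dla", "sodium") %in% names(cfg$lifestyle_effects))
  )
  if (any(cfg$cohort_sizes < 100L)) {
    stop("all cohort_sizes must be >= 100", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d variants in %d AR(1) blocks (latent r = %.2f), MAF in [%.2f, %.2f]\n",
              x$n_variants, x$n_blocks, x$block_r, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  architecture: rho_causal = %g, h2 = %g; GWAS n = %d\n",
              x$rho_causal, x$h2, x$n_gwas))
  cat(sprintf("  cohorts: %s; obesity = BMI >= %g\n",
              paste(x$cohort_sizes, collapse = "/"), x$obesity_threshold))
  invisible(x)
}

block_assignment <- function(cfg) {
  sizes <- rep(cfg$n_variants %/% cfg$n_blocks, cfg$n_blocks)
  extra <- cfg$n_variants %% cfg$n_blocks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(cfg$n_blocks), times = sizes)
}

# Dosage matrix (n x m, values 0/1/2) from a latent AR(1) Gaussian:
# z_1 = e_1, z_k = r z_{k-1} + sqrt(1-r^2) e_k gives corr(z_j, z_k) = r^|j-k|
# within a block; dosage = qbinom(pnorm(z), 2, maf) thresholds the latent
# value at the Binomial(2, maf) quantiles, so marginal genotype frequencies
# are exactly the Hardy-Weinberg proportions at the target MAF while the
# latent correlation carries the LD (attenuated by discretization).
latent_dosages <- function(n, maf, block, r) {
  m <- length(maf)
  z <- matrix(rnorm(n * m), n, m)
  if (r > 0 && m > 1) {
    s <- sqrt(1 - r^2)
    for (k in 2:m) {
      if (block[k] == block[k - 1L]) z[, k] <- r * z[, k - 1L] + s * z[, k]
    }
  }
  u <- pnorm(z)
  d <- matrix(0, n, m)
  for (k in seq_len(m)) d[, k] <- qbinom(u[, k], 2L, maf[k])
  d
}

# Variant metadata is a property of the configuration, not of a single panel:
# every cohort simulated from the same cfg shares ids, positions, alleles,
# MAFs and imputation quality, exactly as cohorts genotyped on the same
# imputation panel would. Derived deterministically from cfg$seed.
variant_metadata <- function(cfg) {
  rng <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(rng)) assign(".Random.seed", rng, globalenv()))
  set.seed(cfg$seed)
  m <- cfg$n_variants
  block <- block_assignment(cfg)
  maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  n_chr <- min(cfg$n_blocks, 22L)
  chr_of_block <- if (n_chr == 1L) rep(1L, cfg$n_blocks) else
    as.integer(cut(seq_len(cfg$n_blocks), breaks = n_chr, labels = FALSE))
  chrom <- chr_of_block[block]
  pos <- integer(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- seq_len(length(idx)) * 5000L
  }
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, m, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), character(1))
  data.frame(
    id = sprintf("var%06d", seq_len(m)), chromosome = chrom, position = pos,
    effect_allele = ea, other_allele = unname(oa),
    maf = maf, imputation_r2 = runif(m, 0.8, 1),
    stringsAsFactors = FALSE
  )
}

#' Simulate an LD-structured genotype dosage panel
#'
#' Thresholds a latent Gaussian at Binomial(2, MAF) quantiles to produce
#' genotype dosages in `{0, 1, 2}`. Within each LD block the latent Gaussian
#' is AR(1) with parameter `cfg$block_r`; blocks are mutually independent.
#' Each variant's minor allele frequency is drawn uniformly from
#' `cfg$maf_range`, and marginal genotype frequencies are exact
#' Hardy-Weinberg proportions by construction.
#'
#' Variant metadata (ids, positions, alleles, MAFs, imputation quality) is
#' derived from `cfg$seed` alone, so every panel simulated from the same
#' configuration shares the same variants -- cohorts are directly scoreable
#' against models built from any other panel of the same configuration.
#'
#' @param cfg A [sim_config()].
#' @param n_samples Number of individuals (>= 2).
#' @param seed Integer seed; the panel is reproducible given `(cfg, seed)`.
#' @param id_prefix Prefix for sample ids (use distinct prefixes to keep the
#'   GWAS sample disjoint from target cohorts).
#' @return A `genotype_panel`: list with `dosages` (n x m numeric matrix,
#'   values in `[0, 2]` or `NA`), `variants` (data.frame: id, chromosome,
#'   position, effect_allele, other_allele, maf, imputation_r2) and `samples`
#'   (data.frame: sample_id, ancestry_ok, sex_consistent).
#' @examples
#' cfg <- sim_config(n_variants = 50, n_blocks = 5, cohort_sizes = c(100, 100))
#' panel <- simulate_panel(cfg, n_samples = 20, seed = 1)
#' dim(panel$dosages)
#' @export
simulate_panel <- function(cfg, n_samples, seed, id_prefix = "S") {
  validate_sim_config(cfg)
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L) {
    stop("n_samples must be an integer >= 2", call. = FALSE)
  }
  variants <- variant_metadata(cfg)
  set.seed(as.integer(seed))
  m <- cfg$n_variants
  block <- block_assignment(cfg)
  maf <- variants$maf

  dos <- latent_dosages(n_samples, maf, block, cfg$block_r)

  samples <- data.frame(
    sample_id = sprintf("%s%06d", id_prefix, seq_len(n_samples)),
    ancestry_ok = TRUE, sex_consistent = TRUE,
    stringsAsFactors = FALSE
  )
  dimnames(dos) <- list(samples$sample_id, variants$id)
  new_genotype_panel(dos, variants, samples)
}

new_genotype_panel <- function(dosages, variants, samples) {
  stopifnot(
    nrow(dosages) == nrow(samples), ncol(dosages) == nrow(variants),
    !anyDuplicated(variants$id)
  )
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d variants; missing: %.2f%%\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Simulate point-normal causal effects
#'
#' Each variant is causal independently with probability `cfg$rho_causal`;
#' causal effects are drawn from `N(0, h2 / (n_variants * rho_causal))` on the
#' standardized-genotype scale, so the summed genetic variance is `h2` in
#' expectation. Non-causal effects are exactly zero.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A `true_effects` list: `beta_true` (numeric, standardized scale) and
#'   `causal_mask` (logical), both of length `cfg$n_variants`.
#' @export
simulate_effects <- function(cfg, seed) {
  validate_sim_config(cfg)
  set.seed(as.integer(seed))
  m <- cfg$n_variants
  causal <- runif(m) < cfg$rho_causal
  beta <- numeric(m)
  if (cfg$h2 > 0 && any(causal)) {
    beta[causal] <- rnorm(sum(causal), 0, sqrt(cfg$h2 / (m * cfg$rho_causal)))
  }
  structure(list(beta_true = beta, causal_mask = causal), class = "true_effects")
}

gamma_pars <- function(mean, sd) list(shape = (mean / sd)^2, rate = mean / sd^2)

# standardized genetic value from dosages (theoretical mean/sd from panel MAF),
# mean-imputing any missing dosage at 2*maf
genetic_value <- function(panel, beta_std) {
  maf <- panel$variants$maf
  sd_j <- sqrt(2 * maf * (1 - maf))
  x <- panel$dosages
  if (anyNA(x)) {
    fill <- matrix(2 * maf, nrow(x), ncol(x), byrow = TRUE)
    x[is.na(x)] <- fill[is.na(x)]
  }
  drop(x %*% (beta_std / sd_j)) - sum(2 * maf * beta_std / sd_j)
}

#' Simulate a cohort phenotype/covariate table
#'
#' BMI is generated from a liability: standardized genetic value (variance
#' `h2`) + age, sex and lifestyle terms + Gaussian noise, then mapped to
#' `bmi_mean + bmi_sd * liability`. The obesity flag is
#' `BMI >= cfg$obesity_threshold`. Lifestyle covariates (leisure-time exercise
#' LTE and daily-life activity DLA in MET-h/d, sodium in g/d) are drawn from
#' gamma distributions matched to typical cohort marginals and are independent
#' of genotype unless `cfg$gxe` is set. Cohort-specific covariate-slope
#' perturbations are drawn with SD `cfg$heterogeneity_tau`.
#'
#' @param panel A `genotype_panel` for the cohort.
#' @param effects A `true_effects` aligned with `panel` (same variants).
#' @param cfg A [sim_config()].
#' @param cohort_id Character label stored in the table.
#' @param seed Integer seed.
#' @return A data.frame (class `cohort_table`) with columns sample_id,
#'   cohort_id, bmi, obesity, age, sex, lte, dla, sodium.
#' @export
simulate_phenotypes <- function(panel, effects, cfg, cohort_id, seed) {
  validate_sim_config(cfg)
  if (length(effects$beta_true) != ncol(panel$dosages)) {
    stop("panel and effects are misaligned: different variant counts", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- nrow(panel$dosages)
  g <- genetic_value(panel, effects$beta_true)

  age <- runif(n, cfg$age_range[1], cfg$age_range[2])
  sex <- ifelse(runif(n) < cfg$sex_ratio, "female", "male")
  lte_p <- gamma_pars(2.6, 4.0)
  dla_p <- gamma_pars(22.6, 14.1)
  sod_p <- gamma_pars(4.0, 0.9)
  lte <- rgamma(n, lte_p$shape, lte_p$rate)
  dla <- rgamma(n, dla_p$shape, dla_p$rate)
  sodium <- rgamma(n, sod_p$shape, sod_p$rate)

  # cohort-specific slope perturbations (identical across cohorts when tau = 0)
  slopes <- cfg$lifestyle_effects[c("lte", "dla", "sodium")] +
    cfg$heterogeneity_tau * rnorm(3)

  age_sd <- (cfg$age_range[2] - cfg$age_range[1]) / sqrt(12)
  z_age <- (age - mean(cfg$age_range)) / max(age_sd, 1e-8)
  z_lte <- (lte - 2.6) / 4.0
  z_dla <- (dla - 22.6) / 14.1
  z_sod <- (sodium - 4.0) / 0.9
  male <- as.numeric(sex == "male")

  fixed <- cfg$age_effect * z_age + cfg$sex_effect * (male - (1 - cfg$sex_ratio)) +
    slopes[["lte"]] * z_lte + slopes[["dla"]] * z_dla + slopes[["sodium"]] * z_sod
  if (cfg$gxe) fixed <- fixed + 0.05 * g * z_lte

  var_fixed <- cfg$age_effect^2 + cfg$sex_effect^2 * cfg$sex_ratio * (1 - cfg$sex_ratio) +
    sum(slopes^2)
  eps_sd <- sqrt(max(0.2, 1 - cfg$h2 - var_fixed))
  liability <- g + fixed + rnorm(n, 0, eps_sd)

  bmi <- cfg$bmi_mean + cfg$bmi_sd * liability
  out <- data.frame(
    sample_id = panel$samples$sample_id,
    cohort_id = as.character(cohort_id),
    bmi = bmi,
    obesity = bmi >= cfg$obesity_threshold,
    age = age, sex = sex,
    lte = lte, dla = dla, sodium = sodium,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Simulate GWAS summary statistics
#'
#' Runs a per-variant simple linear regression of BMI on dosage and reports
#' marginal effect, standard error, p-value, sample size and imputation R^2.
#' The panel/phenotype pair should come from a discovery sample disjoint from
#' any target cohort.
#'
#' @param panel A `genotype_panel`.
#' @param pheno The matching `cohort_table` (same samples, same order).
#' @return A data.frame (class `summary_stats`) with columns id, chromosome,
#'   position, effect_allele, other_allele, beta_marginal, se, p_value, n,
#'   imputation_r2. Constant dosage columns get `NA` effect and `p = 1`, with
#'   a warning.
#' @export
simulate_gwas <- function(panel, pheno) {
  if (!identical(panel$samples$sample_id, pheno$sample_id)) {
    stop("panel and phenotype table are misaligned on samples", call. = FALSE)
  }
  n <- nrow(panel$dosages)
  if (n < 3L) stop("need at least 3 samples for per-variant regression", call. = FALSE)
  x <- panel$dosages
  y <- pheno$bmi

  # per-variant OLS on observed (non-missing) dosages, fully vectorized
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0
  nj <- colSums(obs)
  if (any(nj < 3L)) stop("some variants have fewer than 3 observed dosages", call. = FALSE)
  xm <- colSums(x0) / nj
  ym <- drop(crossprod(obs, y)) / nj
  sxx <- colSums(x0^2) - nj * xm^2
  sxy <- drop(crossprod(x0, y)) - nj * xm * ym
  syy <- drop(crossprod(obs, y^2)) - nj * ym^2

  const <- sxx < 1e-10
  beta <- sxy / sxx
  sigma2 <- pmax(0, (syy - beta * sxy) / (nj - 2))
  se <- sqrt(sigma2 / sxx)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df = nj - 2)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  if (any(const)) {
    warning(sprintf("%d constant dosage column(s): beta set to NA, p to 1", sum(const)))
    beta[const] <- NA_real_
    se[const] <- NA_real_
    p[const] <- 1
  }
  out <- data.frame(
    id = panel$variants$id,
    chromosome = panel$variants$chromosome,
    position = panel$variants$position,
    effect_allele = panel$variants$effect_allele,
    other_allele = panel$variants$other_allele,
    beta_marginal = beta, se = se, p_value = p,
    n = as.integer(nj), imputation_r2 = panel$variants$imputation_r2,
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Inject QC failures into a genotype panel
#'
#' Adds uniform missingness, overwrites selected variants with
#' heterozygote-depleted genotype distributions (so they fail the exact
#' Hardy-Weinberg test) and marks selected variants with imputation R^2 below
#' 0.3, producing inputs that exercise the QC filters.
#'
#' @param panel A `genotype_panel`.
#' @param missing_rate Per-entry missingness probability in `[0, 1)`.
#' @param n_hwe_violators Number of variants to overwrite with het-depleted
#'   genotypes (0/2 only, allele frequency preserved).
#' @param n_low_r2 Number of variants whose imputation R^2 is set below 0.3.
#' @param seed Integer seed.
#' @return The corrupted `genotype_panel`, with attributes `injected_hwe` and
#'   `injected_low_r2` giving the variant ids touched.
#' @export
corrupt_panel <- function(panel, missing_rate = 0, n_hwe_violators = 0L,
                          n_low_r2 = 0L, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1,
            n_hwe_violators >= 0, n_low_r2 >= 0)
  set.seed(as.integer(seed))
  dos <- panel$dosages
  n <- nrow(dos); m <- ncol(dos)
  variants <- panel$variants

  hwe_ids <- character(0)
  if (n_hwe_violators > 0L) {
    j_hwe <- sample.int(m, min(n_hwe_violators, m))
    for (j in j_hwe) {
      p <- variants$maf[j]
      dos[, j] <- 2 * rbinom(n, 1L, p)  # no heterozygotes, frequency preserved
    }
    hwe_ids <- variants$id[j_hwe]
  }
  r2_ids <- character(0)
  if (n_low_r2 > 0L) {
    j_r2 <- sample.int(m, min(n_low_r2, m))
    variants$imputation_r2[j_r2] <- runif(length(j_r2), 0.05, 0.29)
    r2_ids <- variants$id[j_r2]
  }
  if (missing_rate > 0) {
    dos[runif(n * m) < missing_rate] <- NA_real_
  }
  out <- new_genotype_panel(dos, variants, panel$samples)
  attr(out, "injected_hwe") <- hwe_ids
  attr(out, "injected_low_r2") <- r2_ids
  out
}
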