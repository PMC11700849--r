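test_that("scoring computes weighted allele sums with allele reconciliation", {
  # single variant, weight 0.5, dosages 0/1/2
  panel <- toy_panel(matrix(c(0, 1, 2), 3, 1), "A", "C")
  model <- toy_model(0.5, "A", "C")
  sc <- pgs_score(panel, model)
  expect_equal(sc$raw_score, c(0, 0.5, 1.0))
  expect_equal(sc$n_alleles_used, rep(2L, 3))

  # swapped alleles: dosage 2 contributes (2 - 2) * w = 0
  model_sw <- toy_model(0.7, "C", "A")
  sc_sw <- pgs_score(panel, model_sw)
  expect_equal(sc_sw$raw_score, c(2, 1, 0) * 0.7)
  expect_equal(attr(sc_sw, "n_flipped"), 1)

  # allele mismatch: variant skipped and counted
  panel2 <- toy_panel(matrix(c(1, 2, 0, 1, 1, 1), 3, 2),
                      c("A", "G"), c("C", "T"))
  model2 <- toy_model(c(1, 1), c("A", "A"), c("C", "C"))
  sc2 <- pgs_score(panel2, model2)
  expect_equal(attr(sc2, "n_skipped"), 1)
  expect_equal(sc2$raw_score, c(1, 2, 0))
  expect_equal(sc2$n_alleles_used, rep(2L, 3))

  expect_error(pgs_score(panel, toy_model(1, "A", "C", ids = "rs99")),
               "no model variant")
})

test_that("scoring matches a brute-force double loop and handles missingness", {
  set.seed(23)
  dos <- matrix(sample(0:2, 100, replace = TRUE), 10, 10)
  dos[cbind(sample(10, 5), sample(10, 5))] <- NA
  ea <- sample(c("A", "G"), 10, replace = TRUE)
  oa <- ifelse(ea == "A", "C", "T")
  panel <- toy_panel(dos, ea, oa)
  # model with mixed orientations: some as-is, some swapped, one mismatch
  w_ea <- ea; w_oa <- oa
  w_ea[3] <- oa[3]; w_oa[3] <- ea[3]       # swapped
  w_ea[7] <- "T"; w_oa[7] <- "G"           # mismatch unless panel matches
  weights <- rnorm(10)
  model <- toy_model(weights, w_ea, w_oa)
  sc <- pgs_score(panel, model)
  expected <- oracle_score(dos, model$weights, panel$variants)
  expect_equal(sc$raw_score, expected, tolerance = 1e-12)

  expect_error(pgs_score(panel, model, missing = "fail"), "missing dosages")

  # linearity: score(w1 + w2) = score(w1) + score(w2) on identical variants
  m1 <- toy_model(weights, ea, oa)
  m2 <- toy_model(rev(weights), ea, oa)
  m12 <- toy_model(weights + rev(weights), ea, oa)
  expect_equal(pgs_score(panel, m12)$raw_score,
               pgs_score(panel, m1)$raw_score + pgs_score(panel, m2)$raw_score,
               tolerance = 1e-12)
})

test_that("normalization is exact within units and modes differ when cohorts shift", {
  sc <- data.frame(sample_id = sprintf("s%d", 1:6),
                   cohort_id = rep(c("a", "b"), each = 3),
                   raw_score = c(1, 2, 3, 11, 12, 13),
                   z_score = NA_real_, n_alleles_used = 2L)
  class(sc) <- c("score_set", "data.frame")
  per <- normalize_scores(sc, "per_cohort")
  expect_equal(per$z_score, rep(c(-1, 0, 1), 2))
  for (u in c("a", "b")) {
    expect_equal(mean(per$z_score[per$cohort_id == u]), 0, tolerance = 1e-9)
    expect_equal(sd(per$z_score[per$cohort_id == u]), 1, tolerance = 1e-9)
  }
  pooled <- normalize_scores(sc, "pooled")
  expect_false(isTRUE(all.equal(per$z_score, pooled$z_score)))
  expect_equal(mean(pooled$z_score), 0, tolerance = 1e-9)

  sc0 <- sc; sc0$raw_score <- 1
  expect_error(normalize_scores(sc0, "per_cohort"), "zero score variance")
})

test_that("adjusted AUC behaves like the rank statistic and respects the null", {
  set.seed(31)
  n <- 2000
  z <- rnorm(n); age <- runif(n, 40, 80); sex <- rbinom(n, 1, 0.5)
  # perfect separation by the score with covariates noise-free
  out_perfect <- z > median(z)
  a1 <- adjusted_auc(z, out_perfect, age * 0, sex * 0)
  expect_equal(a1$auc, 1.0)

  # null: score independent of outcome stays within the 99% null band
  out_null <- rbinom(n, 1, 0.3) == 1
  a0 <- adjusted_auc(z, out_null, age, sex)
  n1 <- sum(out_null); n0 <- n - n1
  band <- 2.58 * sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(a0$auc - 0.5), band + 0.02)

  # identity with Mann-Whitney U on the fitted linear predictor
  out <- rbinom(n, 1, plogis(z - 1)) == 1
  fit <- glm(out ~ z + age + sex, family = binomial())
  lp <- fit$linear.predictors
  a <- adjusted_auc(z, out, age, sex)
  u <- sum(rank(lp)[out]) - sum(out) * (sum(out) + 1) / 2
  expect_equal(a$auc, u / (sum(out) * sum(!out)), tolerance = 1e-12)
  expect_true(a$ci_low < a$auc && a$auc < a$ci_high)

  # invariance under affine transformation of the score
  a_aff <- adjusted_auc(3 * z + 7, out, age, sex)
  expect_equal(a_aff$auc, a$auc, tolerance = 1e-9)

  expect_error(adjusted_auc(z, rep(TRUE, n), age, sex), "both outcome classes")
})

test_that("inverse-normal transform is a monotone, normalizing rank map", {
  y <- int_transform(c(1, 2, 3))
  expect_equal(y[2], 0, tolerance = 1e-12)
  expect_equal(y[1], -y[3], tolerance = 1e-12)
  expect_true(all(diff(y) > 0))

  set.seed(41)
  x <- rexp(5000)  # heavily skewed input
  yt <- int_transform(x)
  # Anderson-Darling-style check via moments and tail quantiles
  expect_lt(abs(mean(yt)), 0.05)
  expect_lt(abs(sd(yt) - 1), 0.05)
  expect_lt(abs(quantile(yt, 0.975) - qnorm(0.975)), 0.1)
  ks <- suppressWarnings(ks.test(yt, "pnorm"))
  expect_gt(ks$p.value, 0.01)

  # invariance under monotone transforms of the input
  expect_equal(int_transform(exp(x)), yt, tolerance = 1e-12)
  expect_error(int_transform(rep(2, 10)), "all values are equal")
})

test_that("adjusted Spearman matches naive computation and calibrates under the null", {
  set.seed(51)
  z <- rnorm(50)
  trait <- exp(0.5 * z + rnorm(50))
  rho_naive <- oracle_spearman(residuals(lm(int_transform(trait) ~ 1)), z)
  res <- adjusted_spearman(z, trait)
  expect_equal(res$rho, rho_naive, tolerance = 1e-12)

  # perfect monotone relation
  expect_equal(adjusted_spearman(z, exp(z))$rho, 1, tolerance = 1e-12)

  # null calibration with covariates
  set.seed(52)
  rej <- mean(replicate(200, {
    zz <- rnorm(80); tr <- rnorm(80); age <- runif(80, 40, 70)
    sex <- rbinom(80, 1, 0.5)
    adjusted_spearman(zz, tr, age = age, sex = sex)$p < 0.05
  }))
  expect_gte(rej, 0.01); expect_lte(rej, 0.11)

  expect_error(adjusted_spearman(z, trait, extra = cbind(z, z)), "rank deficient")
})

test_that("model selection picks the dominant model and reports all candidates", {
  cfg <- small_cfg(n_variants = 100L, n_blocks = 10L, rho_causal = 0.3,
                   h2 = 0.5, seed = 61L)
  panel <- simulate_panel(cfg, 1200, seed = 62)
  eff <- simulate_effects(cfg, seed = 63)
  ph <- simulate_phenotypes(panel, eff, cfg, "train", seed = 64)
  causal_ids <- panel$variants$id[eff$causal_mask]
  sd_j <- sqrt(2 * panel$variants$maf * (1 - panel$variants$maf))
  good <- pgstrat:::new_pgs_model(
    "causal", "pt", list(p_threshold = 1, r2_threshold = 1),
    data.frame(variant_id = causal_ids,
               chromosome = panel$variants$chromosome[eff$causal_mask],
               position = panel$variants$position[eff$causal_mask],
               effect_allele = panel$variants$effect_allele[eff$causal_mask],
               other_allele = panel$variants$other_allele[eff$causal_mask],
               weight = (eff$beta_true / sd_j)[eff$causal_mask],
               stringsAsFactors = FALSE))
  null_ids <- !eff$causal_mask
  bad <- pgstrat:::new_pgs_model(
    "noise", "pt", list(p_threshold = 1, r2_threshold = 0.1),
    data.frame(variant_id = panel$variants$id[null_ids],
               chromosome = panel$variants$chromosome[null_ids],
               position = panel$variants$position[null_ids],
               effect_allele = panel$variants$effect_allele[null_ids],
               other_allele = panel$variants$other_allele[null_ids],
               weight = rnorm(sum(null_ids), 0, 0.01),
               stringsAsFactors = FALSE))
  sel <- select_best(list(good, bad), panel, ph)
  expect_identical(sel$best_model_id, "causal")
  expect_equal(nrow(sel$report), 2)
  expect_true(all(sel$report$auc >= 0 & sel$report$auc <= 1))
})

test_that("per-cohort z-scores from a shared generative model are exchangeable", {
  # Kruskal-Wallis across cohorts should be non-significant in >= 90/100 reps
  set.seed(71)
  nonsig <- mean(replicate(100, {
    raw <- rnorm(600)
    sc <- data.frame(sample_id = sprintf("s%d", 1:600),
                     cohort_id = rep(c("a", "b", "c"), each = 200),
                     raw_score = raw + rep(c(0, 2, -1), each = 200),  # cohort shifts
                     z_score = NA_real_, n_alleles_used = 2L)
    class(sc) <- c("score_set", "data.frame")
    z <- normalize_scores(sc, "per_cohort")$z_score
    kruskal.test(z, factor(sc$cohort_id))$p.value > 0.05
  }))
  expect_gte(nonsig, 0.90)
})
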