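make_ld_panel <- function(n_variants = 12L, n_blocks = 3L, n = 400L,
                          block_r = 0.7, seed = 1L, maf = c(0.1, 0.5)) {
  cfg <- small_cfg(n_variants = n_variants, n_blocks = n_blocks,
                   block_r = block_r, maf_range = maf, seed = seed)
  simulate_panel(cfg, n, seed = seed + 1L)
}

test_that("clumping keeps the low-p representative and its LD-free peers", {
  # 3 variants: r2(1,2) high, r2(1,3) ~ 0; p = (1e-8, 1e-6, 0.5)
  set.seed(3)
  z <- rnorm(2000)
  d1 <- qbinom(pnorm(z), 2, 0.5)
  d2 <- qbinom(pnorm(0.999 * z + sqrt(1 - 0.999^2) * rnorm(2000)), 2, 0.5)
  d3 <- qbinom(pnorm(rnorm(2000)), 2, 0.5)
  panel <- toy_panel(cbind(d1, d2, d3), rep("A", 3), rep("C", 3))
  stopifnot(cor(d1, d2)^2 > 0.8, cor(d1, d3)^2 < 0.05)
  ss <- toy_sumstats(panel, beta = c(0.5, 0.4, 0.1), se = rep(0.05, 3),
                     p = c(1e-8, 1e-6, 0.5))
  ld <- ld_reference(panel, window_size = 3)
  m <- clump_threshold(ss, ld, p_threshold = 5e-1, r2_threshold = 0.8)
  expect_identical(m$weights$variant_id, c("rs1", "rs3"))
  expect_equal(m$weights$weight, c(0.5, 0.1))
})

test_that("no pruning occurs when thresholds are permissive", {
  panel <- make_ld_panel()
  ph <- simulate_phenotypes(panel, simulate_effects(small_cfg(n_variants = 12L,
                                                              n_blocks = 3L,
                                                              seed = 1L), 2),
                            small_cfg(n_variants = 12L, n_blocks = 3L, seed = 1L),
                            "c", 3)
  ss <- simulate_gwas(panel, ph)
  ld <- ld_reference(panel, window_size = 4)
  m <- clump_threshold(ss, ld, p_threshold = 1, r2_threshold = 1)
  expect_equal(nrow(m$weights), 12)
  ord <- match(m$weights$variant_id, ss$id)
  expect_equal(m$weights$weight, ss$beta_marginal[ord])
})

test_that("clumping errors when nothing passes the p threshold", {
  panel <- make_ld_panel()
  ss <- toy_sumstats(panel, beta = rep(0.1, 12), se = rep(0.05, 12),
                     p = rep(0.5, 12))
  ld <- ld_reference(panel, window_size = 4)
  expect_error(clump_threshold(ss, ld, 5e-8, 0.2), class = "pgstrat_empty_model")
})

test_that("clumping matches exhaustive greedy enumeration on random instances", {
  set.seed(17)
  for (rep in 1:100) {
    m <- sample(4:12, 1)
    n <- 300
    r <- runif(1, 0, 0.9)
    cfg <- small_cfg(n_variants = m, n_blocks = sample(1:3, 1), block_r = r,
                     maf_range = c(0.15, 0.5), seed = 1000 + rep)
    panel <- simulate_panel(cfg, n, seed = 2000 + rep)
    p <- runif(m)^3
    beta <- rnorm(m, 0, 0.2)
    ss <- toy_sumstats(panel, beta, rep(0.05, m), p)
    ld <- ld_reference(panel, window_size = m)  # single window = dense r2
    p_th <- sample(c(0.05, 0.2, 0.5, 1), 1)
    r2_th <- sample(c(0.1, 0.3, 0.6, 0.9), 1)
    r2mat <- suppressWarnings(cor(panel$dosages))^2
    expected <- oracle_clump(p, panel$variants$chromosome,
                             panel$variants$position, r2mat, p_th, r2_th)
    got <- tryCatch(
      clump_threshold(ss, ld, p_th, r2_th),
      pgstrat_empty_model = function(e) NULL
    )
    if (is.null(got)) {
      expect_length(expected, 0)
    } else {
      expect_identical(got$weights$variant_id,
                       panel$variants$id[sort(expected)])
    }
  }
})

test_that("clumped set is invariant to summary-stat row order", {
  panel <- make_ld_panel(seed = 5)
  ph <- simulate_phenotypes(panel,
                            simulate_effects(small_cfg(n_variants = 12L, n_blocks = 3L,
                                                       seed = 5L), 2),
                            small_cfg(n_variants = 12L, n_blocks = 3L, seed = 5L),
                            "c", 3)
  ss <- simulate_gwas(panel, ph)
  ld <- ld_reference(panel, window_size = 6)
  m1 <- clump_threshold(ss, ld, 1, 0.3)
  set.seed(9)
  ss_shuffled <- ss[sample(nrow(ss)), ]
  m2 <- clump_threshold(ss_shuffled, ld, 1, 0.3)
  expect_identical(m1$weights, m2$weights)
})

test_that("model grids have the expected composition", {
  panel <- make_ld_panel(n_variants = 30L, n_blocks = 3L, seed = 7)
  cfg <- small_cfg(n_variants = 30L, n_blocks = 3L, seed = 7L)
  ph <- simulate_phenotypes(panel, simulate_effects(cfg, 2), cfg, "c", 3)
  ss <- simulate_gwas(panel, ph)
  ld <- ld_reference(panel, window_size = 10)

  custom <- build_pt_grid(ss, ld, p_thresholds = 0.5, r2_thresholds = 0.3)
  expect_length(custom, 1)

  grid <- build_pt_grid(ss, ld)
  hp <- lapply(grid, function(m) unlist(m$hyperparams[c("p_threshold", "r2_threshold")]))
  expect_equal(length(unique(hp)), length(grid))  # pairwise distinct

  # empty grid points are retained as explicit failures
  ss_weak <- ss; ss_weak$p_value <- pmax(ss_weak$p_value, 0.1)
  grid2 <- build_pt_grid(ss_weak, ld)
  failures <- Filter(function(m) !inherits(m, "pgs_model"), grid2)
  expect_gt(length(failures), 0)
  expect_length(grid2, 24)
  expect_true(all(grepl("no variant passes",
                        vapply(failures, `[[`, character(1), "error"))))

  lgrid <- build_ldpred_grid(ss, ld, h2 = 0.3, n = 400,
                             rho_grid = c(1, 0.1), n_iter = 50, burnin = 10)
  expect_length(lgrid, 2)
  rhos <- vapply(lgrid, function(m) m$hyperparams$rho, numeric(1))
  expect_equal(unname(rhos), c(1, 0.1))
})

test_that("infinitesimal shrinkage solves the windowed ridge system", {
  # LD-free: elementwise shrinkage n*h2 / (n*h2 + M)
  cfg <- small_cfg(n_variants = 20L, n_blocks = 20L, block_r = 0, seed = 31L)
  panel <- simulate_panel(cfg, 500, seed = 32)
  ph <- simulate_phenotypes(panel, simulate_effects(cfg, 2), cfg, "c", 3)
  ss <- simulate_gwas(panel, ph)
  ld0 <- ld_reference(panel, window_size = 20)
  ld0$R[[1]] <- diag(20)  # exact identity LD
  h2 <- 0.25; n <- 5000
  m_inf <- ldpred_inf(ss, ld0, h2 = h2, n = n)
  shrink <- n * h2 / (n * h2 + 20)
  ord <- match(m_inf$weights$variant_id, ss$id)
  expect_equal(m_inf$weights$weight, ss$beta_marginal[ord] * shrink,
               tolerance = 1e-10)

  # 2-variant window: explicit hand inversion
  R <- matrix(c(1, 0.6, 0.6, 1), 2)
  beta <- c(0.3, -0.1)
  lambda <- 2 / (n * h2)
  A <- R + diag(lambda, 2)
  det_a <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  hand <- c(A[2, 2] * beta[1] - A[1, 2] * beta[2],
            -A[2, 1] * beta[1] + A[1, 1] * beta[2]) / det_a
  panel2 <- toy_panel(matrix(c(0, 1, 2, 1, 0, 2, 1, 1), 4, 2), c("A", "G"), c("C", "T"))
  ss2 <- toy_sumstats(panel2, beta, c(0.05, 0.05), c(1e-4, 0.2))
  ld2 <- ld_reference(panel2, window_size = 2)
  ld2$R[[1]] <- R
  m2 <- ldpred_inf(ss2, ld2, h2 = h2, n = n)
  expect_equal(m2$weights$weight, hand, tolerance = 1e-10)

  # h2 -> 0+ limit: weights vanish
  m0 <- ldpred_inf(ss, ld0, h2 = 1e-8, n = n)
  expect_lt(max(abs(m0$weights$weight)), 1e-4 * max(abs(ss$beta_marginal)))
})

test_that("Gibbs weights are deterministic given the seed", {
  panel <- make_ld_panel(n_variants = 20L, n_blocks = 2L, seed = 41)
  cfg <- small_cfg(n_variants = 20L, n_blocks = 2L, seed = 41L)
  ph <- simulate_phenotypes(panel, simulate_effects(cfg, 2), cfg, "c", 3)
  ss <- simulate_gwas(panel, ph)
  ld <- ld_reference(panel, window_size = 10)
  g1 <- ldpred_gibbs(ss, ld, rho = 0.1, h2 = 0.3, n = 2000, seed = 99)
  g2 <- ldpred_gibbs(ss, ld, rho = 0.1, h2 = 0.3, n = 2000, seed = 99)
  expect_identical(g1$weights, g2$weights)
  g3 <- ldpred_gibbs(ss, ld, rho = 0.1, h2 = 0.3, n = 2000, seed = 100)
  expect_false(identical(g1$weights$weight, g3$weights$weight))
})

test_that("Gibbs at rho = 1 agrees with the infinitesimal closed form", {
  cfg <- small_cfg(n_variants = 30L, n_blocks = 30L, block_r = 0, seed = 51L)
  panel <- simulate_panel(cfg, 400, seed = 52)
  ph <- simulate_phenotypes(panel, simulate_effects(cfg, 2), cfg, "c", 3)
  ss <- simulate_gwas(panel, ph)
  ld <- ld_reference(panel, window_size = 30)
  ld$R[[1]] <- diag(30)
  h2 <- 0.3; n <- 5000
  m_inf <- ldpred_inf(ss, ld, h2 = h2, n = n)
  g <- ldpred_gibbs(ss, ld, rho = 1, h2 = h2, n = n,
                    n_iter = 600, burnin = 100, seed = 53)
  # with identity LD the post-burn-in draws are independent N(mean, v_post),
  # so the Monte-Carlo SE of each averaged weight is sqrt(v_post / kept)
  v_post <- 1 / (1 / (h2 / 30) + n)
  mc_se <- sqrt(v_post / 500)
  zdev <- abs(g$weights$weight - m_inf$weights$weight) / mc_se
  expect_lt(mean(zdev), 3)
  expect_gt(cor(g$weights$weight, m_inf$weights$weight), 0.95)
})

test_that("posterior inclusion matches the closed-form Bayes factor", {
  # analytic identity of the update formula
  betas <- c(-0.2, -0.01, 0, 0.005, 0.08, 0.4)
  pip <- ldpred_pip(betas, n = 2000, rho = 0.03, sigma2 = 0.01)
  expect_equal(pip, oracle_pip(betas, 2000, 0.03, 0.01), tolerance = 1e-8)
  expect_equal(ldpred_pip(0.3, n = 1000, rho = 1, sigma2 = 0.01), 1)

  # the sampler's realized single-variant inclusion frequency converges to it
  panel <- toy_panel(matrix(c(0, 1, 2, 1, 1, 0, 2, 2), 8, 1), "A", "C")
  beta_hat <- 0.06
  ss <- toy_sumstats(panel, beta_hat, 0.02, 0.003)
  ld <- ld_reference(panel, window_size = 1)
  n <- 2000; rho <- 0.3; h2 <- 0.02
  sigma2 <- h2 / (1 * rho)
  g <- ldpred_gibbs(ss, ld, rho = rho, h2 = h2, n = n,
                    n_iter = 4100, burnin = 100, seed = 7)
  p_true <- ldpred_pip(beta_hat, n, rho, sigma2)
  mc_se <- sqrt(p_true * (1 - p_true) / 4000)
  expect_lt(abs(g$weights$inclusion - p_true), 4 * mc_se + 0.02)
})

test_that("Gibbs recovers causal structure better than marginal betas", {
  cfg <- small_cfg(n_variants = 400L, n_blocks = 8L, rho_causal = 0.05,
                   h2 = 0.3, seed = 61L)
  panel <- simulate_panel(cfg, 6000, seed = 62)
  eff <- simulate_effects(cfg, seed = 63)
  ph <- simulate_phenotypes(panel, eff, cfg, "gwas", seed = 64)
  ss <- simulate_gwas(panel, ph)
  ld <- ld_reference(panel, window_size = 100)
  g <- ldpred_gibbs(ss, ld, rho = 0.05, h2 = 0.3, n = 6000, seed = 65)
  ord <- match(g$weights$variant_id, panel$variants$id)
  expect_gt(cor(g$weights$weight, eff$beta_true[ord]),
            cor(ss$beta_marginal, eff$beta_true))
})

test_that("scoring-format serialization round-trips losslessly", {
  w <- c(0.123456789012345, -1e-7, 3.5)
  model <- toy_model(w, c("A", "G", "T"), c("C", "T", "A"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_pgs_model(model, path)
  back <- read_pgs_model(path)
  expect_identical(back$weights$variant_id, model$weights$variant_id)
  expect_identical(back$weights$effect_allele, model$weights$effect_allele)
  expect_identical(back$weights$weight, model$weights$weight)
  expect_equal(back$hyperparams$p_threshold, 1)
  expect_identical(back$method, "pt")
  expect_identical(back$model_id, "toy")
})
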