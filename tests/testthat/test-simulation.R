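# A small configuration used throughout: fewer individuals and SNPs than the
# study design, same structure.
smallConfig <- function(...) {
  simConfig(n_individuals = 4000L, n_snps = 200L, n_iv = 12L, n_h_only = 20L,
            n_y_only = 20L, n_both = 20L, n_extra_null = 400L, n_blocks = 10L,
            ...)
}

test_that("the fixed truth is deterministic and respects the class design", {
  cfg <- smallConfig(p2 = 2L, seed = 5L)
  t1 <- drawEffects(cfg)
  t2 <- drawEffects(cfg)
  expect_identical(t1@beta_GH, t2@beta_GH)
  expect_identical(t1@snp_class, t2@snp_class)
  expect_identical(t1@true_b, t2@true_b)

  cls <- t1@snp_class
  expect_equal(sum(cls == "iv_valid") + sum(cls == "iv_invalid"), 12L)
  expect_equal(sum(cls == "iv_invalid"), round(0.3 * 12))
  # valid IVs affect the covariates only; invalid IVs are pleiotropic
  expect_true(all(t1@beta_GY[cls == "iv_valid"] == 0))
  expect_true(all(t1@beta_GY[cls == "iv_invalid"] != 0))
  expect_true(all(t1@beta_GH[cls == "null", ] == 0))
  expect_true(all(t1@beta_GY[cls == "null"] == 0))
  expect_true(all(t1@beta_GH[cls == "extra_null", ] == 0))
  # null focal SNPs live in the second half of the blocks
  m <- cfg@n_snps
  expect_true(all(t1@block_id[seq_len(m)][cls[seq_len(m)] == "null"] > 5))
  expect_true(all(t1@block_id[seq_len(m)][!cls[seq_len(m)] %in%
                                            c("null", "extra_null")] <= 5))
})

test_that("pleiotropy correlation is honoured by the bivariate effect draw", {
  for (rho in c(0, 0.5, -0.5)) {
    cfg <- simConfig(n_snps = 400L, n_both = 200L, n_h_only = 60L,
                     n_y_only = 60L, n_iv = 30L, n_extra_null = 0L,
                     rho = rho, seed = 17L)
    tr <- drawEffects(cfg)
    idx <- tr@snp_class %in% c("both", "iv_invalid")
    r <- cor(tr@beta_GY[idx], tr@beta_GH[idx, 1])
    expect_lt(abs(r - rho), 3 / sqrt(sum(idx)))
  }
})

test_that("genotype generation is centred with faithful marginals and block structure", {
  cfg <- smallConfig(p2 = 1L, seed = 6L, genotype_mode = "block_correlated")
  tr <- drawEffects(cfg)
  G <- genGenotypes(cfg, tr, seed = 7L)
  expect_lt(max(abs(colMeans(G))), 1e-12)
  expect_equal(unname(attr(G, "sxx")), unname(colSums(G^2)), tolerance = 1e-8)
  # marginal variance ~ 2 maf (1 - maf)
  v_emp <- apply(G[, 1:50], 2, var)
  v_th <- 2 * tr@maf[1:50] * (1 - tr@maf[1:50])
  expect_lt(max(abs(v_emp - v_th) / v_th), 0.2)
  # focal blocks are correlated within, not across; extra nulls independent
  m <- cfg@n_snps
  same_block <- which(tr@block_id == tr@block_id[1])
  rw <- cor(G[, same_block])
  expect_gt(mean(rw[upper.tri(rw)]), 0.02)
  cross <- abs(cor(G[, 1], G[, m + 1]))
  expect_lt(cross, 3 / sqrt(nrow(G)) + 0.02)

  # zero block correlation reduces to the independent mode statistically
  cfg0 <- smallConfig(p2 = 1L, seed = 6L, genotype_mode = "block_correlated",
                      block_corr = 0)
  G0 <- genGenotypes(cfg0, drawEffects(cfg0), seed = 8L)
  rr <- cor(G0[, 1:20])
  expect_lt(max(abs(rr[upper.tri(rr)])), 4 / sqrt(nrow(G0)))
})

test_that("phenotypes satisfy the variance budget", {
  cfg <- simConfig(n_individuals = 100000L, n_snps = 200L, n_iv = 12L,
                   n_h_only = 20L, n_y_only = 20L, n_both = 20L,
                   n_extra_null = 0L, n_blocks = 10L, p2 = 2L, seed = 9L)
  tr <- drawEffects(cfg)
  G <- genGenotypes(cfg, tr, seed = 10L)
  ph <- genPhenotypes(G, tr, seed = 11L)
  for (k in 1:2) {
    err_share <- tr@structural@cov_EH[k, k] / var(ph$H[, k])
    expect_equal(err_share, cfg@error_share, tolerance = 0.02 / 0.1)
    conf_share <- tr@structural@beta_UH[k]^2 / var(ph$H[, k])
    expect_equal(conf_share, cfg@confounder_share, tolerance = 0.05 / 0.4)
  }
  expect_equal(tr@var_EY / var(ph$Y), cfg@error_share, tolerance = 0.02 / 0.1)
  expect_equal(tr@structural@beta_UY^2 / var(ph$Y), cfg@confounder_share,
               tolerance = 0.05 / 0.4)
})

test_that("removing the confounder decouples the outcome from U", {
  cfg <- smallConfig(p2 = 1L, seed = 12L)
  tr <- drawEffects(cfg)
  tr@structural@beta_UH[] <- 0
  tr@structural@beta_UY <- 0
  G <- genGenotypes(cfg, tr, seed = 13L)
  ph <- genPhenotypes(G, tr, seed = 14L)
  expect_lt(abs(cor(ph$Y, ph$U)), 3 / sqrt(cfg@n_individuals))
})

test_that("the conditional GWAS equals exact least squares", {
  cfg <- smallConfig(p2 = 2L, seed = 18L)
  tr <- drawEffects(cfg)
  G <- genGenotypes(cfg, tr, seed = 19L)
  ph <- genPhenotypes(G, tr, seed = 20L)
  panel <- runGwas(G, ph$H, ph$Y)
  for (i in sample(ncol(G), 20)) {
    fit <- lm(ph$Y ~ G[, i] + ph$H)
    expect_equal(panel@beta[i, 1], unname(coef(fit)[2]), tolerance = 1e-8)
    expect_equal(panel@se[i, 1], unname(sqrt(diag(vcov(fit)))[2]),
                 tolerance = 1e-8)
    fm <- lm(ph$H[, 2] ~ G[, i])
    expect_equal(panel@beta[i, 3], unname(coef(fm)[2]), tolerance = 1e-8)
    expect_equal(panel@se[i, 3], unname(sqrt(diag(vcov(fm)))[2]),
                 tolerance = 1e-8)
  }
})

test_that("a noise-free single-SNP outcome is recovered without error", {
  set.seed(22)
  G <- colliderMR:::cpp_dosage_independent(500, 0.3, TRUE)
  Y <- drop(2 * G[, 1])
  H <- matrix(rnorm(500), ncol = 1)
  panel <- runGwas(G, H, Y + 1e-8 * rnorm(500))
  expect_equal(panel@beta[1, 1], 2, tolerance = 1e-4)
  expect_lt(panel@se[1, 1], 1e-6)
})

test_that("the experiment is reproducible and its report is internally consistent", {
  cfg <- smallConfig(p2 = 1L, seed = 23L)
  ex1 <- suppressWarnings(runExperiment(cfg, 3, methods = "cml", n_starts = 2))
  ex2 <- suppressWarnings(runExperiment(cfg, 3, methods = "cml", n_starts = 2))
  expect_identical(ex1$report@rates, ex2$report@rates)
  expect_identical(ex1$b$cml, ex2$b$cml)
  expect_true(all(ex1$report@rates$rate >= 0 & ex1$report@rates$rate <= 1))
  # corrected-equals-raw degenerate case: power before equals power after
  res <- ex1
  res$reject_after$cml <- res$reject_before
  rep2 <- evaluateReplicates(res)
  before <- rep2@rates[rep2@rates$stage == "before", ]
  after <- rep2@rates[rep2@rates$stage == "after", ]
  expect_equal(after$rate, before$rate[match(after$class, before$class)])
})
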