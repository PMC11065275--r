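test_that("the theoretical bias slope follows the structural parameters", {
  # no confounder effect on Y means no collider bias
  m0 <- structuralModel(beta_UH = c(1, 2), beta_UY = 0, var_U = 1,
                        cov_EH = diag(2))
  expect_equal(trueSlope(m0), c(0, 0))
  # scalar case: -beta_UY Var(U) beta_UH / (beta_UH^2 Var(U) + Var(E_H))
  m1 <- structuralModel(beta_UH = 1, beta_UY = 1, var_U = 1, cov_EH = 1)
  expect_equal(trueSlope(m1), -0.5)
  # V/J terms: verified against a direct matrix evaluation
  set.seed(2)
  p2 <- 2; q <- 2; p1 <- 3
  B_VH <- matrix(rnorm(p2 * q), p2)
  A <- matrix(rnorm(q * q), q); cov_V <- crossprod(A) + diag(q)
  Bj <- matrix(rnorm(p1 * p1), p1); cov_J <- crossprod(Bj) + diag(p1)
  cov_JV <- matrix(rnorm(p1 * q), p1) * 0.2
  mm <- structuralModel(beta_UH = c(0.5, -0.3), beta_UY = 0.7, var_U = 2,
                        cov_EH = diag(c(0.5, 0.8)), B_VH = B_VH, cov_V = cov_V,
                        cov_J = cov_J, cov_JV = cov_JV)
  Marg <- tcrossprod(c(0.5, -0.3)) * 2 + diag(c(0.5, 0.8)) +
    B_VH %*% cov_V %*% t(B_VH) -
    B_VH %*% t(cov_JV) %*% solve(cov_J) %*% cov_JV %*% t(B_VH)
  expect_equal(trueSlope(mm), drop(-0.7 * 2 * solve(Marg) %*% c(0.5, -0.3)))
})

test_that("the bias slope matches the empirical conditional-GWAS regression", {
  # regressing (conditional beta - direct effect) on the covariate effects
  # across SNPs recovers the slope
  set.seed(14)
  n <- 20000; m <- 40; p2 <- 2
  G <- colliderMR:::cpp_dosage_independent(n, runif(m, 0.2, 0.5), TRUE)
  beta_GH <- matrix(rnorm(m * p2, sd = 0.05), m)
  beta_GY <- rnorm(m, sd = 0.05)
  beta_UH <- c(0.6, -0.4); beta_UY <- 0.8
  U <- rnorm(n)
  H <- G %*% beta_GH + tcrossprod(U, beta_UH) +
    matrix(rnorm(n * p2, sd = sqrt(0.5)), n)
  Y <- drop(G %*% beta_GY) + beta_UY * U + rnorm(n, sd = 0.7)
  sm <- structuralModel(beta_UH = beta_UH, beta_UY = beta_UY, var_U = 1,
                        cov_EH = diag(0.5, p2))
  # per-SNP structural noise includes the other SNPs' genetic background
  Zg <- G %*% beta_GH
  b_eff <- drop(-solve(cov(Zg) + tcrossprod(beta_UH) + diag(0.5, p2),
                       drop(cov(Zg, G %*% beta_GY)) + beta_UH * beta_UY))
  panel <- runGwas(G, H, Y)
  fit <- lm(panel@beta[, 1] - beta_GY ~ panel@beta[, -1] - 1)
  expect_lt(max(abs(unname(coef(fit)) - b_eff)), 0.12)
  # with a tiny genetic background the plain structural formula agrees too
  expect_equal(b_eff, trueSlope(sm), tolerance = 0.1)
})

test_that("single-SNP correction reproduces the propagation arithmetic", {
  sl <- new("SlopeEstimate", method = "ivw", b_hat = 0.5,
            cov_b = matrix(0.01, 1, 1), intercept = numeric(0),
            diagnostics = list())
  out <- correctSnp(1.0, 0.3, 0.4, 0.2, sl)
  expect_equal(out$beta_corrected, 0.8)
  expect_equal(out$se_corrected^2, 0.102, tolerance = 1e-12)
  expect_equal(out$z, 0.8 / sqrt(0.102))

  sl2 <- new("SlopeEstimate", method = "ivw", b_hat = c(0.5, -0.2),
             cov_b = diag(0, 2), intercept = numeric(0), diagnostics = list())
  out2 <- correctSnp(1.0, 0.3, c(0.4, 1.0), c(0, 0), sl2)
  expect_equal(out2$beta_corrected, 1.0)

  # null slope: identity
  sl0 <- new("SlopeEstimate", method = "ivw", b_hat = 0,
             cov_b = matrix(0, 1, 1), intercept = numeric(0),
             diagnostics = list())
  out0 <- correctSnp(1.0, 0.3, 0.4, 0.2, sl0)
  expect_equal(out0$beta_corrected, 1.0)
  expect_equal(out0$se_corrected, 0.3)

  slbad <- new("SlopeEstimate", method = "ivw", b_hat = c(0, 0),
               cov_b = diag(2), intercept = numeric(0), diagnostics = list())
  slbad@cov_b <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_error(correctSnp(1, 0.3, c(0, 0), c(0, 0), slbad), "positive semidefinite")
})

test_that("panel correction is linear in the slope and never shrinks the SE", {
  set.seed(15)
  m <- 50
  panel <- new("AlignedPanel", variant_ids = paste0("s", 1:m),
               chrom = rep("1", m), pos = 1:m,
               effect_allele = rep("A", m), other_allele = rep("G", m),
               beta = cbind(rnorm(m), rnorm(m), rnorm(m)),
               se = matrix(runif(3 * m, 0.05, 0.2), m),
               trait_names = c("y", "h1", "h2"), n_vector = rep(1000L, 3))
  mk <- function(b) new("SlopeEstimate", method = "ivw", b_hat = b,
                        cov_b = diag(0.01, 2), intercept = numeric(0),
                        diagnostics = list())
  b1 <- c(0.3, -0.1); b2 <- c(-0.2, 0.4)
  c12 <- correctPanel(panel, mk(b1 + b2), quiet = TRUE)
  c1 <- correctPanel(panel, mk(b1), quiet = TRUE)
  # sequential correction holding the covariate betas fixed
  panel2 <- panel
  panel2@beta[, 1] <- c1$beta_corrected
  c2 <- correctPanel(panel2, mk(b2), quiet = TRUE)
  expect_equal(c2$beta_corrected, c12$beta_corrected, tolerance = 1e-12)
  expect_true(all(c12$se_corrected >= c12$se_raw))

  c0 <- correctPanel(panel, new("SlopeEstimate", method = "ivw",
                                b_hat = c(0, 0), cov_b = diag(0, 2),
                                intercept = numeric(0), diagnostics = list()),
                     quiet = TRUE)
  expect_equal(c0$beta_corrected, c0$beta_raw)
  expect_equal(c0$se_corrected, c0$se_raw)
})

test_that("locus counting maps significant SNPs to blocks", {
  blocks <- data.frame(chrom = c("1", "1", "2"),
                       start = c(0L, 1000L, 0L), end = c(1000L, 2000L, 500L))
  rec <- data.frame(variant_id = paste0("s", 1:5), chrom = c("1", "1", "1", "2", "2"),
                    pos = c(10L, 500L, 1500L, 100L, 600L),
                    pvalue = c(1e-10, 1e-9, 1e-12, 0.5, 1e-9))
  out <- countLoci(rec, blocks, p_threshold = 5e-8)
  expect_equal(out$n_sig_snps, 4L)
  # s1+s2 share block 1; s3 in block 2; s5 outside all blocks -> singleton
  expect_equal(out$n_sig_loci, 3L)
  expect_equal(countLoci(rec[rec$pvalue > 1e-3, , drop = FALSE], blocks),
               list(n_sig_snps = 0L, n_sig_loci = 0L))
  out_all <- countLoci(rec, blocks, p_threshold = 1)
  expect_equal(out_all$n_sig_snps, 5L)
  bad <- blocks; bad$start[2] <- 500L
  expect_error(countLoci(rec, bad), "non-overlapping")
})

test_that("leave-one-out flags the instrument driving the fit", {
  set.seed(16)
  bH <- rnorm(12, sd = 1)
  by <- 0.5 * bH + rnorm(12, sd = 0.02)
  by[12] <- by[12] + 3
  p <- makeIVPanel(by, bH, se = matrix(0.05, 12, 2))
  tab <- looSensitivity(p, mvmrIVW)
  expect_equal(which.max(tab$influence), 12L)

  # exchangeable identical instruments: no influence
  p_dup <- makeIVPanel(rep(0.5, 8), rep(1, 8), se = matrix(0.1, 8, 2))
  tab2 <- looSensitivity(p_dup, mvmrIVW)
  expect_true(all(tab2$influence < 1e-10))
})
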