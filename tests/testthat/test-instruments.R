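test_that("LD pruning keeps independent variants and deduplicates", {
  v <- data.frame(variant_id = paste0("s", 1:10), chrom = "1",
                  pos = 1:10 * 100L, stringsAsFactors = FALSE)
  r0 <- matrix(0, 10, 10); diag(r0) <- 1
  expect_identical(ldPrune(v, r0), v$variant_id)

  r_dup <- r0
  r_dup[1, 2] <- r_dup[2, 1] <- 1
  kept <- ldPrune(v, r_dup)
  expect_true("s1" %in% kept && !"s2" %in% kept)

  v_bad <- v[c(2, 1, 3:10), ]
  expect_error(ldPrune(v_bad, r0), "sorted")
})

test_that("pruning matches a brute-force pairwise check on block-correlated data", {
  set.seed(21)
  m <- 100
  G <- colliderMR:::cpp_dosage_blocks(600, runif(m, 0.1, 0.5),
                                      rep(1:5, each = 20), 0.5, TRUE)
  r2 <- cor(G)^2
  v <- data.frame(variant_id = paste0("s", 1:m), chrom = "1", pos = 1:m,
                  stringsAsFactors = FALSE)
  kept <- ldPrune(v, r2, window = 50, r2_threshold = 0.001)
  idx <- match(kept, v$variant_id)
  for (a in seq_along(idx)) for (b in seq_len(a - 1L)) {
    if (idx[a] - idx[b] <= 50)
      expect_lt(r2[idx[a], idx[b]], 0.001)
  }
  # appending SNPs far downstream leaves the earlier choice unchanged
  v2 <- rbind(v, data.frame(variant_id = "far", chrom = "2", pos = 1L))
  r2fun <- function(i, j) if (i <= m && j <= m) r2[i, j] else 0
  expect_identical(ldPrune(v2[order(v2$chrom, v2$pos), ], r2fun,
                           window = 50, r2_threshold = 0.001)[
                             seq_along(kept)], kept)
})

test_that("instrument selection applies the minimum covariate p-value rule", {
  z <- c(10, 0.5, 7, 9, 8, 0.2)
  beta <- cbind(rnorm(6, sd = 0.01), z * 0.01)
  se <- matrix(0.01, 6, 2)
  panel <- new("AlignedPanel", variant_ids = paste0("s", 1:6),
               chrom = rep("1", 6), pos = 1:6,
               effect_allele = rep("A", 6), other_allele = rep("G", 6),
               beta = beta, se = se, trait_names = c("y", "h"),
               n_vector = c(1000L, 1000L))
  ivp <- selectIVs(panel, p_threshold = 5e-8)
  expect_setequal(variantIds(ivp), c("s1", "s3", "s4", "s5"))
  expect_setequal(variantIds(selectIVs(panel, p_threshold = 1)), paste0("s", 1:6))
  expect_error(selectIVs(panel, p_threshold = 1e-30), "insufficient instruments")
})

test_that("overlap correlation recovers independence and self-correlation", {
  set.seed(31)
  m <- 2000
  # two traits on disjoint samples: independent z-scores
  z1 <- rnorm(m); z2 <- rnorm(m)
  panel <- new("AlignedPanel", variant_ids = paste0("s", 1:m),
               chrom = rep("1", m), pos = 1:m,
               effect_allele = rep("A", m), other_allele = rep("G", m),
               beta = cbind(z1, z2) * 0.01, se = matrix(0.01, m, 2),
               trait_names = c("y", "h"), n_vector = c(1000L, 1000L))
  oc <- estimateOverlapCorrelation(panel)
  expect_lt(abs(overlapMatrix(oc)[1, 2]), 0.05)

  # outcome duplicated as covariate: correlation ~ 1
  panel2 <- panel
  panel2@beta[, 2] <- panel@beta[, 1]
  oc2 <- estimateOverlapCorrelation(panel2)
  expect_gt(overlapMatrix(oc2)[1, 2], 0.99)

  expect_error(estimateOverlapCorrelation(alignedSubsetForTest(panel, 1:100)),
               "at least 200")
})

test_that("overlap correlation matches individual-level error correlation in one sample", {
  set.seed(32)
  n <- 5000; m <- 1200
  G <- colliderMR:::cpp_dosage_independent(n, runif(m, 0.1, 0.5), TRUE)
  U <- rnorm(n)
  H <- 0.8 * U + rnorm(n, sd = 0.6)
  Y <- 0.5 * H + 0.8 * U + rnorm(n, sd = 0.5)
  panel <- runGwas(G, matrix(H), Y)
  oc <- estimateOverlapCorrelation(panel)
  # oracle: correlation of per-SNP error z-scores equals the correlation of
  # G'e_Y and G'e_H across the shared sample, e_Y the residual of Y on H
  eY <- resid(lm(Y ~ H))
  eH <- H - mean(H)
  rho_oracle <- cor(crossprod(G, eY), crossprod(G, eH))
  mc_se <- 3 / sqrt(oc@n_pairs[1, 2])
  expect_lt(abs(overlapMatrix(oc)[1, 2] - rho_oracle), mc_se + 0.05)
})

test_that("sigma assembly reproduces the covariance arithmetic and repairs degeneracy", {
  S <- assembleSigma(matrix(c(0.1, 0.2), 1), matrix(c(1, 0.5, 0.5, 1), 2))[[1]]
  expect_equal(S, matrix(c(0.01, 0.01, 0.01, 0.04), 2), tolerance = 1e-12)
  Sd <- assembleSigma(matrix(c(0.1, 0.2), 1), diag(2))[[1]]
  expect_equal(Sd, diag(c(0.01, 0.04)), tolerance = 1e-12)
  expect_message(Ssing <- assembleSigma(matrix(c(0.1, 0.1), 1),
                                        matrix(1, 2, 2)), "ridge-repaired")
  expect_gt(min(eigen(Ssing[[1]], only.values = TRUE)$values), 0)
  expect_error(assembleSigma(matrix(c(-0.1, 0.2), 1), diag(2)), "positive")
})

test_that("conditional F reduces to mean squared z for one exposure and flags collinearity", {
  ivp <- makeIVPanel(c(0, 0), beta_h = c(3, 4), se = matrix(1, 2, 2))
  expect_equal(conditionalF(ivp)$F, 12.5)

  # duplicated exposures carry no conditional strength
  set.seed(41)
  bH <- rnorm(10)
  ivp2 <- makeIVPanel(rnorm(10), cbind(bH, bH + rnorm(10, sd = 1e-4)),
                      se = matrix(0.1, 10, 3))
  f2 <- conditionalF(ivp2)
  expect_true(all(f2$weak))
  expect_true(all(f2$F < 1))

  # strong independent instruments per exposure
  bH3 <- cbind(c(rnorm(10, 5, 0.1), rnorm(10, 0, 0.1)),
               c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1)))
  ivp3 <- makeIVPanel(rnorm(20), bH3, se = matrix(0.1, 20, 3))
  expect_true(all(conditionalF(ivp3)$F > 10))
})
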