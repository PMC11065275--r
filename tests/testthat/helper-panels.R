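# Builders for synthetic panels used across the test files.

# An IVPanel from explicit outcome/covariate effects, unit or supplied SEs,
# and an overlap correlation (identity by default).
makeIVPanel <- function(beta_y, beta_h, se = NULL, corr = NULL, n_min = 100000L) {
  l <- length(beta_y)
  beta_h <- as.matrix(beta_h)
  p2 <- ncol(beta_h)
  if (is.null(se)) se <- matrix(1, l, p2 + 1)
  if (is.null(corr)) corr <- diag(p2 + 1)
  ivp <- new("IVPanel", iv_ids = paste0("iv", seq_len(l)),
             beta_hat = cbind(beta_y, beta_h, deparse.level = 0),
             se = se, sigma = list(), n_min = as.integer(n_min),
             p2 = as.integer(p2))
  assembleSigma(ivp, corr)
}

# A random panel drawn from the summary-data model itself: instrument effects
# on the covariates and a true slope, K invalid IVs with free outcome
# intercepts, estimates drawn with the per-IV covariances.
makeModelPanel <- function(l, p2, K, seed = NULL, se_range = c(0.05, 0.3),
                           overlap = 0.2, r_sd = 2) {
  if (!is.null(seed)) set.seed(seed)
  bH <- matrix(rnorm(l * p2), l)
  b <- rnorm(p2)
  r <- numeric(l)
  if (K > 0) r[sample(l, K)] <- rnorm(K, sd = r_sd)
  se <- matrix(runif(l * (p2 + 1), se_range[1], se_range[2]), l)
  C <- diag(p2 + 1)
  C[C == 0] <- overlap
  sig <- lapply(seq_len(l), function(j) C * outer(se[j, ], se[j, ]))
  bh <- t(vapply(seq_len(l), function(j) {
    mu <- c(sum(b * bH[j, ]) + r[j], bH[j, ])
    mu + drop(rnorm(p2 + 1) %*% chol(sig[[j]]))
  }, numeric(p2 + 1)))
  panel <- new("IVPanel", iv_ids = paste0("iv", seq_len(l)), beta_hat = bh,
               se = se, sigma = list(), n_min = 100000L, p2 = as.integer(p2))
  list(panel = assembleSigma(panel, C), b = b, r = r, bH = bH)
}

# A random TraitPanel records data.frame.
makeRecords <- function(n, seed = 1, chrom = "1") {
  set.seed(seed)
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, n, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), character(1))
  beta <- rnorm(n, sd = 0.1)
  se <- runif(n, 0.01, 0.1)
  data.frame(variant_id = sprintf("rs%04d", seq_len(n)), chrom = chrom,
             pos = seq_len(n) * 1000L, effect_allele = ea, other_allele = oa,
             beta = beta, se = se, pvalue = 2 * pnorm(-abs(beta / se)),
             n = 10000L, stringsAsFactors = FALSE)
}

alignedSubsetForTest <- function(panel, idx) colliderMR:::alignedSubset(panel, idx)

with_seed_test <- function(seed, expr) colliderMR:::with_seed(seed, expr)

# Flip the allele coding of whole records (swap alleles, negate beta).
flipRecords <- function(records, idx = seq_len(nrow(records))) {
  tmp <- records$effect_allele[idx]
  records$effect_allele[idx] <- records$other_allele[idx]
  records$other_allele[idx] <- tmp
  records$beta[idx] <- -records$beta[idx]
  records
}
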