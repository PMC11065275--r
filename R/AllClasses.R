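#' @useDynLib colliderMR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats pnorm qnorm pchisq qchisq rnorm runif rbinom setNames
#'   coef lm median cor var sd quantile optim
#' @importFrom utils read.delim write.table combn head
NULL

VALID_ALLELES <- c("A", "C", "G", "T")

#' GWAS summary statistics for a single trait
#'
#' A validated container for one tab-separated GWAS summary table: per-variant
#' effect estimates on a declared effect allele, their standard errors,
#' p-values and sample sizes. The `role` slot distinguishes the conditional
#' outcome GWAS (trait adjusted for the heritable covariates) from a covariate
#' GWAS.
#'
#' @slot trait_name single character, trait label.
#' @slot role `"outcome_conditional"` or `"covariate"`.
#' @slot records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, `n`.
#' @slot sample_size trait-level sample size (maximum of per-record `n`).
#'
#' @export
setClass("TraitPanel",
  representation(trait_name = "character", role = "character",
                 records = "data.frame", sample_size = "integer"))

setValidity("TraitPanel", function(object) {
  msg <- character()
  if (length(object@trait_name) != 1L) msg <- c(msg, "trait_name must be length 1")
  if (!object@role %in% c("outcome_conditional", "covariate"))
    msg <- c(msg, "role must be 'outcome_conditional' or 'covariate'")
  req <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "beta", "se", "pvalue", "n")
  miss <- setdiff(req, names(object@records))
  if (length(miss)) msg <- c(msg, paste("records missing columns:",
                                        paste(miss, collapse = ", ")))
  if (!length(msg)) {
    r <- object@records
    if (anyDuplicated(r$variant_id))
      msg <- c(msg, "duplicate variant_id within panel")
    if (any(r$se <= 0)) msg <- c(msg, "all se must be > 0")
    if (any(r$pvalue <= 0 | r$pvalue > 1)) msg <- c(msg, "pvalue must lie in (0, 1]")
    if (!all(r$effect_allele %in% VALID_ALLELES) ||
        !all(r$other_allele %in% VALID_ALLELES))
      msg <- c(msg, "alleles must be single characters in {A,C,G,T}")
    if (nrow(r) && object@sample_size < max(r$n))
      msg <- c(msg, "sample_size must be >= max per-record n")
  }
  if (length(msg)) msg else TRUE
})

#' Allele-harmonized multi-trait effect panel
#'
#' Holds per-SNP effect estimates and standard errors for the conditional
#' outcome GWAS (column 1) and the `p2` covariate GWAS (columns 2..p2+1), all
#' expressed on a shared effect-allele orientation (the outcome panel's
#' coding). Variants absent from any trait are dropped on construction, so
#' the matrices are complete.
#'
#' @slot variant_ids character vector, length m.
#' @slot chrom,pos per-variant coordinates (1-based positions).
#' @slot effect_allele,other_allele shared allele orientation.
#' @slot beta m x (p2+1) effect matrix, column 1 = conditional outcome betas.
#' @slot se m x (p2+1) positive standard-error matrix.
#' @slot trait_names column labels (outcome first).
#' @slot n_vector per-trait sample sizes.
#'
#' @export
setClass("AlignedPanel",
  representation(variant_ids = "character", chrom = "character",
                 pos = "integer", effect_allele = "character",
                 other_allele = "character", beta = "matrix", se = "matrix",
                 trait_names = "character", n_vector = "integer"))

setValidity("AlignedPanel", function(object) {
  msg <- character()
  m <- length(object@variant_ids)
  p1 <- ncol(object@beta)
  if (p1 < 2L) msg <- c(msg, "need the outcome plus at least one covariate (p2 >= 1)")
  if (nrow(object@beta) != m || !identical(dim(object@beta), dim(object@se)))
    msg <- c(msg, "beta/se dimensions inconsistent with variant_ids")
  if (anyNA(object@beta) || anyNA(object@se))
    msg <- c(msg, "no missing cells allowed")
  if (any(object@se <= 0)) msg <- c(msg, "all se must be > 0")
  if (anyDuplicated(object@variant_ids)) msg <- c(msg, "duplicate variant ids")
  if (length(object@trait_names) != p1 || length(object@n_vector) != p1)
    msg <- c(msg, "trait_names/n_vector must have p2+1 entries")
  if (length(msg)) msg else TRUE
})

#' Sample-overlap correlation of GWAS summary statistics
#'
#' Pairwise correlations of estimation errors across the outcome and
#' covariate GWAS, estimated from null z-scores and repaired to the nearest
#' positive semidefinite matrix with unit diagonal.
#'
#' @slot corr (p2+1) x (p2+1) symmetric correlation matrix.
#' @slot n_pairs integer matrix of null-SNP counts used per trait pair.
#'
#' @export
setClass("OverlapCorrelation",
  representation(corr = "matrix", n_pairs = "matrix"))

setValidity("OverlapCorrelation", function(object) {
  msg <- character()
  C <- object@corr
  if (!isSymmetric(unname(C), tol = 1e-8)) msg <- c(msg, "corr must be symmetric")
  if (any(abs(diag(C) - 1) > 1e-8)) msg <- c(msg, "corr diagonal must be 1")
  if (any(abs(C) > 1 + 1e-8)) msg <- c(msg, "corr entries must lie in [-1, 1]")
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-6)
    msg <- c(msg, "corr must be positive semidefinite")
  if (length(msg)) msg else TRUE
})

#' Selected instruments with per-IV covariance matrices
#'
#' The l selected instruments' effect vectors (outcome first, then the p2
#' covariates) together with the per-IV covariance matrices Sigma_j whose
#' off-diagonals carry the sample-overlap correlations.
#'
#' @slot iv_ids instrument identifiers, length l.
#' @slot beta_hat l x (p2+1) effect matrix, column 1 = conditional outcome.
#' @slot se l x (p2+1) standard errors.
#' @slot sigma list of l positive-definite (p2+1) x (p2+1) matrices.
#' @slot n_min minimum sample size across the GWAS datasets (the BIC N).
#' @slot p2 number of covariates.
#'
#' @export
setClass("IVPanel",
  representation(iv_ids = "character", beta_hat = "matrix", se = "matrix",
                 sigma = "list", n_min = "integer", p2 = "integer"))

setValidity("IVPanel", function(object) {
  msg <- character()
  l <- nrow(object@beta_hat)
  p2 <- object@p2
  if (ncol(object@beta_hat) != p2 + 1L) msg <- c(msg, "beta_hat must have p2+1 columns")
  if (l < p2 + 1L)
    msg <- c(msg, sprintf("need l >= p2 + 1 instruments (have l = %d, p2 = %d)", l, p2))
  if (!length(object@sigma) %in% c(0L, l))
    msg <- c(msg, "sigma must be empty (pending assembly) or have one matrix per IV")
  if (!length(msg) && length(object@sigma)) {
    for (j in seq_len(l)) {
      S <- object@sigma[[j]]
      if (!isSymmetric(unname(S), tol = 1e-8) ||
          min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
        msg <- c(msg, sprintf("sigma[[%d]] is not symmetric positive definite", j))
        break
      }
      if (any(abs(diag(S) - object@se[j, ]^2) > 1e-6 * diag(S))) {
        msg <- c(msg, sprintf("diag(sigma[[%d]]) must equal squared SEs", j))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Constrained-ML fit at a fixed number of invalid instruments
#'
#' @slot K constrained number of invalid IVs.
#' @slot b fitted slope vector (length p2).
#' @slot betaH fitted instrument-covariate effects (l x p2).
#' @slot r fitted instrument-outcome intercepts; exactly zero off the invalid
#'   set.
#' @slot invalid_set indices (1-based) of the K invalid IVs.
#' @slot loglik maximised log-likelihood.
#' @slot bic BIC(K) = -2 loglik + K log(N).
#' @slot converged logical convergence flag.
#' @slot n_starts_agreeing number of random starts reaching the best optimum.
#'
#' @export
setClass("CMLFitK",
  representation(K = "integer", b = "numeric", betaH = "matrix", r = "numeric",
                 invalid_set = "integer", loglik = "numeric", bic = "numeric",
                 converged = "logical", n_starts_agreeing = "integer"))

setValidity("CMLFitK", function(object) {
  msg <- character()
  if (length(object@invalid_set) != object@K)
    msg <- c(msg, "|invalid_set| must equal K")
  # r may be exactly zero for an invalid IV whose residual vanishes, so only
  # an upper bound holds; nonzero r off the invalid set is forbidden
  if (sum(object@r != 0) > object@K)
    msg <- c(msg, "more nonzero r than K")
  if (any(object@r[setdiff(seq_along(object@r), object@invalid_set)] != 0))
    msg <- c(msg, "nonzero r outside the invalid set")
  if (length(msg)) msg else TRUE
})

#' A slope (bias vector) estimate with its covariance
#'
#' @slot method one of `"cml"`, `"ivw"`, `"egger"`, `"lasso"`, `"median"`,
#'   `"dho"`.
#' @slot b_hat estimated slope vector (length p2).
#' @slot cov_b p2 x p2 symmetric PSD covariance of `b_hat`.
#' @slot intercept Egger intercept (directional-pleiotropy diagnostic), or
#'   length 0.
#' @slot diagnostics named list of method-specific diagnostics.
#'
#' @export
setClass("SlopeEstimate",
  representation(method = "character", b_hat = "numeric", cov_b = "matrix",
                 intercept = "numeric", diagnostics = "list"))

setValidity("SlopeEstimate", function(object) {
  msg <- character()
  if (!object@method %in% c("cml", "ivw", "egger", "lasso", "median", "dho"))
    msg <- c(msg, "unknown method")
  p2 <- length(object@b_hat)
  if (!identical(dim(object@cov_b), c(p2, p2)))
    msg <- c(msg, "cov_b must be p2 x p2")
  else {
    if (!isSymmetric(unname(object@cov_b), tol = 1e-6))
      msg <- c(msg, "cov_b must be symmetric")
    if (min(eigen((object@cov_b + t(object@cov_b)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values) < -1e-8 * max(1, max(abs(object@cov_b))))
      msg <- c(msg, "cov_b must be positive semidefinite")
  }
  if (object@method == "dho" && p2 != 1L)
    msg <- c(msg, "dho is only defined for p2 = 1")
  if (length(msg)) msg else TRUE
})

#' MVMR-cML result with BIC model selection
#'
#' Extends [SlopeEstimate-class] with the selected number of invalid IVs, the
#' valid-IV set, and the per-K log-likelihood/BIC table.
#'
#' @slot K_hat selected number of invalid IVs (argmin BIC; ties to smaller K).
#' @slot valid_set 1-based indices of IVs with r = 0 at K_hat.
#' @slot per_k list of [CMLFitK-class], one per candidate K.
#' @slot N_used the sample size N used in the BIC penalty.
#'
#' @export
setClass("CMLResult", contains = "SlopeEstimate",
  representation(K_hat = "integer", valid_set = "integer", per_k = "list",
                 N_used = "integer"))

setValidity("CMLResult", function(object) {
  msg <- character()
  bics <- vapply(object@per_k, function(f) f@bic, numeric(1))
  ks <- vapply(object@per_k, function(f) f@K, integer(1))
  best <- ks[which(bics == min(bics))]
  if (object@K_hat != min(best))
    msg <- c(msg, "K_hat must minimise BIC with ties to the smallest K")
  sel <- object@per_k[[match(object@K_hat, ks)]]
  l <- length(sel@r)
  if (!setequal(c(object@valid_set, sel@invalid_set), seq_len(l)))
    msg <- c(msg, "valid_set and invalid_set must partition the IVs")
  if (length(msg)) msg else TRUE
})

#' Structural model for the theoretical bias slope
#'
#' Parameters of the linear structural model linking the SNP, the heritable
#' covariates H (possibly adjusted for extra covariates V in their own GWAS),
#' the confounder U, the non-heritable covariates J and the outcome Y. The
#' theoretical bias slope b follows from these via [trueSlope()].
#'
#' @slot beta_UH confounder effects on H (length p2).
#' @slot beta_UY confounder effect on Y.
#' @slot var_U confounder variance (> 0).
#' @slot cov_EH p2 x p2 covariance of the H noise terms.
#' @slot B_VH p2 x q effects of the V covariates on H (q may be 0).
#' @slot cov_V q x q covariance of V.
#' @slot cov_J p1 x p1 covariance of J (p1 may be 0).
#' @slot cov_JV p1 x q cross-covariance of J and V.
#' @slot beta_HY causal effects of H on Y (length p2).
#' @slot beta_JY effects of J on Y (length p1).
#'
#' @export
setClass("StructuralModel",
  representation(beta_UH = "numeric", beta_UY = "numeric", var_U = "numeric",
                 cov_EH = "matrix", B_VH = "matrix", cov_V = "matrix",
                 cov_J = "matrix", cov_JV = "matrix", beta_HY = "numeric",
                 beta_JY = "numeric"))

setValidity("StructuralModel", function(object) {
  msg <- character()
  p2 <- length(object@beta_UH)
  q <- ncol(object@B_VH)
  p1 <- nrow(object@cov_J)
  if (object@var_U <= 0) msg <- c(msg, "var_U must be > 0")
  if (!identical(dim(object@cov_EH), c(p2, p2))) msg <- c(msg, "cov_EH must be p2 x p2")
  if (nrow(object@B_VH) != p2) msg <- c(msg, "B_VH must have p2 rows")
  if (!identical(dim(object@cov_V), c(q, q))) msg <- c(msg, "cov_V must be q x q")
  if (!identical(dim(object@cov_JV), c(p1, q))) msg <- c(msg, "cov_JV must be p1 x q")
  if (length(object@beta_HY) != p2) msg <- c(msg, "beta_HY must have length p2")
  if (length(object@beta_JY) != p1) msg <- c(msg, "beta_JY must have length p1")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Study conditions for the synthetic GWAS generator: a cohort of unrelated
#' individuals, 1000 focal SNPs of which 30 serve as instruments, 50 affect
#' the covariates only, 50 the outcome only and 50 both (with optionally
#' correlated pleiotropy), plus 3000 extra null SNPs on a separate chromosome
#' whose z-scores feed the sample-overlap correlation estimate. The shared
#' confounder accounts for 40% of the variance of each trait and each noise
#' term for 10% of the total variance.
#'
#' @slot n_individuals cohort size per replicate.
#' @slot n_snps number of focal SNPs.
#' @slot n_iv number of instruments.
#' @slot n_h_only,n_y_only,n_both SNP class counts.
#' @slot n_extra_null extra null SNPs (separate chromosome) for overlap
#'   correlation estimation.
#' @slot p2 number of heritable covariates.
#' @slot rho pleiotropy correlation between effects on Y and on H1 for the
#'   "both" SNPs.
#' @slot invalid_fraction fraction of the instruments that are invalid
#'   (pleiotropic).
#' @slot confounder_share confounder share of the total variance.
#' @slot error_share noise share of the total variance.
#' @slot genotype_mode `"independent"` or `"block_correlated"`.
#' @slot block_corr latent within-block exchangeable correlation.
#' @slot n_blocks number of LD blocks for the focal SNPs.
#' @slot maf_range minor-allele-frequency range (uniform draw).
#' @slot seed base seed; fixes the SNP effects and all replicate streams.
#'
#' @export
setClass("SimConfig",
  representation(n_individuals = "integer", n_snps = "integer", n_iv = "integer",
                 n_h_only = "integer", n_y_only = "integer", n_both = "integer",
                 n_extra_null = "integer", p2 = "integer", rho = "numeric",
                 invalid_fraction = "numeric", confounder_share = "numeric",
                 error_share = "numeric", genotype_mode = "character",
                 block_corr = "numeric", n_blocks = "integer",
                 maf_range = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@n_h_only + object@n_y_only + object@n_both > object@n_snps)
    msg <- c(msg, "SNP class counts exceed n_snps")
  if (!object@genotype_mode %in% c("independent", "block_correlated"))
    msg <- c(msg, "genotype_mode must be 'independent' or 'block_correlated'")
  if (object@error_share <= 0 || object@error_share >= 1 ||
      object@confounder_share <= 0 || object@confounder_share >= 1)
    msg <- c(msg, "variance shares must lie in (0, 1)")
  if (object@error_share + object@confounder_share >= 1)
    msg <- c(msg, "error_share + confounder_share must be < 1")
  if (length(object@maf_range) != 2 || object@maf_range[1] <= 0 ||
      object@maf_range[2] > 0.5 || object@maf_range[1] > object@maf_range[2])
    msg <- c(msg, "maf_range must be increasing within (0, 0.5]")
  n_invalid <- round(object@invalid_fraction * object@n_iv)
  if (object@n_iv - n_invalid > object@n_h_only)
    msg <- c(msg, "more valid IVs than covariate-only SNPs")
  if (n_invalid > object@n_both)
    msg <- c(msg, "more invalid IVs than pleiotropic SNPs")
  if (length(msg)) msg else TRUE
})

#' Fixed simulation truth
#'
#' Per-SNP classes and effect sizes, drawn once per configuration and held
#' fixed across replicates, together with the implied structural model and
#' theoretical bias slope.
#'
#' @slot snp_class per-SNP label: `iv_valid`, `iv_invalid`, `h_only`,
#'   `y_only`, `both`, `null`, or `extra_null`.
#' @slot maf per-SNP minor allele frequencies (focal then extra-null SNPs).
#' @slot block_id per-SNP LD block (0 for extra-null SNPs).
#' @slot beta_GH (n_snps + n_extra_null) x p2 matrix of SNP effects on H.
#' @slot beta_GY true direct SNP effects on Y.
#' @slot beta_HY causal effects of H on Y.
#' @slot var_EY outcome noise variance from the variance budget.
#' @slot structural implied [StructuralModel-class] (covariate noise
#'   variances live in its `cov_EH`).
#' @slot true_b population bias slope of the generator.
#' @slot config the generating [SimConfig-class].
#'
#' @export
setClass("SimTruth",
  representation(snp_class = "character", maf = "numeric", block_id = "integer",
                 beta_GH = "matrix", beta_GY = "numeric", beta_HY = "numeric",
                 var_EY = "numeric", structural = "StructuralModel",
                 true_b = "numeric", config = "SimConfig"))

#' Simulation evaluation report
#'
#' Rejection-rate summaries (type-I error and power, before and after bias
#' correction) per SNP class, extreme-SNP rows, and per-method slope
#' summaries across replicates.
#'
#' @slot rates data.frame: `class`, `method`, `stage`, `rate`, `sd`,
#'   `n_snps`.
#' @slot extremes data.frame of the SNPs with the greatest power increase
#'   and decrease per method.
#' @slot slopes data.frame of per-method slope summaries (mean, SD, mean SE,
#'   truth).
#' @slot n_replicates number of replicates evaluated.
#'
#' @export
setClass("EvalReport",
  representation(rates = "data.frame", extremes = "data.frame",
                 slopes = "data.frame", n_replicates = "integer"))

setValidity("EvalReport", function(object) {
  if (nrow(object@rates) &&
      any(object@rates$rate < 0 | object@rates$rate > 1, na.rm = TRUE))
    "rates must lie in [0, 1]" else TRUE
})

setValidity("SimTruth", function(object) {
  msg <- character()
  cls <- object@snp_class
  ok <- c("iv_valid", "iv_invalid", "h_only", "y_only", "both", "null", "extra_null")
  if (!all(cls %in% ok)) msg <- c(msg, "unknown snp_class label")
  if (length(object@maf) != length(cls) || nrow(object@beta_GH) != length(cls))
    msg <- c(msg, "per-SNP slots must share length")
  # invalid IVs are pleiotropic, valid IVs affect the covariates only
  if (any(object@beta_GY[cls == "iv_valid"] != 0))
    msg <- c(msg, "valid IVs must have zero direct effect on Y")
  if (any(object@beta_GY[cls == "iv_invalid"] == 0))
    msg <- c(msg, "invalid IVs must have nonzero direct effect on Y")
  if (length(msg)) msg else TRUE
})
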