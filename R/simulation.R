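#' Simulation configuration constructor
#'
#' Defaults reproduce the study conditions of the type-I error / power
#' simulation: 1000 focal SNPs in 20 LD blocks (non-null SNPs confined to
#' the first half of the blocks), 30 instruments, 50 covariate-only /
#' 50 outcome-only / 50 pleiotropic SNPs, 3000 extra null SNPs on a separate
#' chromosome for overlap-correlation estimation, a shared confounder
#' accounting for 40% of the variance of each trait, and noise terms
#' contributing 10% of each total variance.
#'
#' @param n_individuals cohort size per replicate (default 50000).
#' @param n_snps,n_iv,n_h_only,n_y_only,n_both,n_extra_null SNP layout.
#' @param p2 number of heritable covariates (1, 2 or 4 in the study design).
#' @param rho pleiotropy correlation for the SNPs affecting both H1 and Y.
#' @param invalid_fraction fraction of instruments that are invalid.
#' @param confounder_share,error_share variance budget shares.
#' @param genotype_mode `"independent"` (default) or `"block_correlated"`.
#' @param block_corr,n_blocks block-exchangeable latent correlation and
#'   number of blocks.
#' @param maf_range uniform MAF range.
#' @param seed base seed fixing the SNP effects and replicate streams.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(n_individuals = 50000L, n_snps = 1000L, n_iv = 30L,
                      n_h_only = 50L, n_y_only = 50L, n_both = 50L,
                      n_extra_null = 3000L, p2 = 1L, rho = 0,
                      invalid_fraction = 0.3, confounder_share = 0.4,
                      error_share = 0.1,
                      genotype_mode = c("independent", "block_correlated"),
                      block_corr = 0.1, n_blocks = 20L,
                      maf_range = c(0.05, 0.5), seed = 1L) {
  genotype_mode <- match.arg(genotype_mode)
  new("SimConfig", n_individuals = as.integer(n_individuals),
      n_snps = as.integer(n_snps), n_iv = as.integer(n_iv),
      n_h_only = as.integer(n_h_only), n_y_only = as.integer(n_y_only),
      n_both = as.integer(n_both), n_extra_null = as.integer(n_extra_null),
      p2 = as.integer(p2), rho = rho, invalid_fraction = invalid_fraction,
      confounder_share = confounder_share, error_share = error_share,
      genotype_mode = genotype_mode, block_corr = block_corr,
      n_blocks = as.integer(n_blocks), maf_range = as.numeric(maf_range),
      seed = as.integer(seed))
}

# Variance-budget algebra: with each trait standardised to total variance 1,
# the confounder contributes confounder_share and the noise error_share of
# the total, leaving the genetic component the remainder. This of-total
# reading reproduces the strong-collider-bias regime of the study design
# (see the methods vignette for the calibration argument).
geneticShare <- function(config) {
  1 - config@error_share - config@confounder_share
}

drawFocalDosages <- function(config, maf, block_id) {
  if (config@genotype_mode == "independent")
    cpp_dosage_independent(config@n_individuals, maf, TRUE)
  else
    cpp_dosage_blocks(config@n_individuals, maf, block_id, config@block_corr, TRUE)
}

#' Draw the fixed simulation truth
#'
#' Assigns SNP classes and positions (non-null SNPs in the first half of the
#' LD blocks, null SNPs in the second half, extra null SNPs on a separate
#' chromosome) and draws all effect sizes. For the pleiotropic SNPs the
#' effects on the outcome and the first covariate are drawn from a bivariate
#' normal with correlation `rho`; all other nonzero effects are standard
#' normal. Valid instruments are sampled from the covariate-only SNPs and
#' invalid ones from the pleiotropic SNPs. Effects are fixed: two calls with
#' the same config are identical, and replicates share the truth.
#'
#' The effects stay exactly as drawn; the confounder loadings and noise
#' variances are solved from the variance budget instead. The genetic
#' variance realised by the draws is measured on a reference genotype sample
#' of 20000 individuals (drawn within the config-seeded stream); each
#' covariate's total variance is then genetic variance / genetic share, with
#' the confounder and noise taking their configured shares of that total,
#' and the outcome's total solves the analogous budget including the
#' mediated covariate contribution and the confounder cross-covariance. The
#' slot `true_b` carries the generator's population bias slope, which
#' augments the structural formula with the polygenic-background covariances
#' (see the methods vignette).
#'
#' @param config a [SimConfig-class].
#' @return A [SimTruth-class].
#' @export
drawEffects <- function(config) {
  with_seed(config@seed, {
    m <- config@n_snps
    total <- m + config@n_extra_null
    p2 <- config@p2
    n_nonnull <- config@n_h_only + config@n_y_only + config@n_both
    if (n_nonnull >= m) stop("need at least one null focal SNP")
    # non-null SNPs live in the first half of the blocks, null SNPs in the
    # second half, so the null SNPs are independent of all causal SNPs
    half <- max(1L, config@n_blocks %/% 2L)
    rest <- config@n_blocks - half
    block_id <- c(sort(rep_len(seq_len(half), n_nonnull)),
                  sort(rep_len(half + seq_len(rest), m - n_nonnull)),
                  rep(0L, config@n_extra_null))
    maf <- runif(total, config@maf_range[1], config@maf_range[2])
    nonnull <- seq_len(n_nonnull)
    cls <- rep("null", total)
    if (config@n_extra_null > 0L) cls[(m + 1):total] <- "extra_null"
    lab <- sample(rep(c("h_only", "y_only", "both"),
                      c(config@n_h_only, config@n_y_only, config@n_both)))
    cls[nonnull] <- lab

    beta_GH <- matrix(0, total, p2)
    beta_GY <- numeric(total)
    h_idx <- which(cls == "h_only")
    y_idx <- which(cls == "y_only")
    b_idx <- which(cls == "both")
    beta_GH[h_idx, ] <- rnorm(length(h_idx) * p2)
    beta_GY[y_idx] <- rnorm(length(y_idx))
    z1 <- rnorm(length(b_idx))
    z2 <- rnorm(length(b_idx))
    beta_GY[b_idx] <- z1
    beta_GH[b_idx, 1] <- config@rho * z1 + sqrt(1 - config@rho^2) * z2
    if (p2 > 1L)
      beta_GH[b_idx, -1] <- rnorm(length(b_idx) * (p2 - 1L))
    beta_HY <- rnorm(p2)

    n_invalid <- as.integer(round(config@invalid_fraction * config@n_iv))
    iv_valid <- sample(h_idx, config@n_iv - n_invalid)
    iv_invalid <- sample(b_idx, n_invalid)
    cls[iv_valid] <- "iv_valid"
    cls[iv_invalid] <- "iv_invalid"

    # Variance budget, solved self-consistently per trait against a
    # reference genotype draw (the effects themselves are the raw draws
    # above, exactly as generated): with genetic variance g_k realised for
    # covariate k, the total Var(H_k) = g_k / genetic_share, the confounder
    # contributes confounder_share and the noise error_share of that total.
    # For the outcome the same shares apply to its realised total, which
    # includes the direct SNP effects, the mediated covariate effects and
    # the confounder cross-covariance (quadratic in sqrt(Var(Y))).
    g_share <- geneticShare(config)
    n_ref <- 20000L
    ref_cfg <- config
    ref_cfg@n_individuals <- n_ref
    G_ref <- drawFocalDosages(ref_cfg, maf[seq_len(m)], block_id[seq_len(m)])
    gvar <- vapply(seq_len(p2), function(k)
      var(drop(G_ref %*% beta_GH[seq_len(m), k])), numeric(1))
    totH <- gvar / g_share
    beta_UH <- sqrt(config@confounder_share * totH)
    var_EH <- config@error_share * totH
    U_ref <- rnorm(n_ref)
    EH_ref <- matrix(rnorm(n_ref * p2), n_ref, p2) *
      rep(sqrt(var_EH), each = n_ref)
    H_ref <- G_ref %*% beta_GH[seq_len(m), , drop = FALSE] +
      tcrossprod(U_ref, beta_UH) + EH_ref
    S_ref <- drop(G_ref %*% beta_GY[seq_len(m)] + H_ref %*% beta_HY)
    VS <- var(S_ref)
    cross <- sum(beta_HY * beta_UH)  # Cov(S, U) with Var(U) = 1
    cs <- sqrt(config@confounder_share)
    # Var(Y) = T solves (1 - conf - err) T = VS + 2 sqrt(conf T) cross
    x <- (cs * cross + sqrt(cs^2 * cross^2 + g_share * VS)) / g_share  # sqrt(T)
    beta_UY <- cs * x
    var_EY <- config@error_share * x^2

    sm <- structuralModel(beta_UH = beta_UH, beta_UY = beta_UY, var_U = 1,
                          cov_EH = diag(var_EH, p2), beta_HY = beta_HY)
    # Population bias slope of the generator. For any tested SNP the other
    # SNPs' contributions to H and Y act as part of the structural noise
    # terms, so the per-SNP structural model has effective covariances
    # Cov(E_H) + Cov(Z_g) and a cross-covariance Cov(Z_g, W_g) between the
    # H- and Y-backgrounds (Z_g, W_g the polygenic components); the slope is
    # the generalised form b = -Cov(Z)^{-1} [beta_UH beta_UY Var(U) +
    # Cov(Z_g, W_g)], which reduces to the plain confounder-only expression
    # when the shared background vanishes.
    Zg <- G_ref %*% beta_GH[seq_len(m), , drop = FALSE]
    Wg <- drop(G_ref %*% beta_GY[seq_len(m)])
    CovZ <- stats::cov(Zg) + tcrossprod(beta_UH) + diag(var_EH, p2)
    CovZW <- drop(stats::cov(Zg, Wg)) + beta_UH * beta_UY
    true_b <- drop(-solve(CovZ, CovZW))
    new("SimTruth", snp_class = cls, maf = maf, block_id = as.integer(block_id),
        beta_GH = beta_GH, beta_GY = beta_GY, beta_HY = beta_HY,
        var_EY = var_EY, structural = sm, true_b = true_b, config = config)
  })
}

#' Generate a replicate's genotype matrix
#'
#' Focal SNPs are drawn per the configured genotype mode (independent
#' Binomial(2, maf) dosages, or block-exchangeable latent-Gaussian dosages
#' dichotomised at the Hardy-Weinberg quantiles); the extra null SNPs are
#' always independent. All columns are centred to sample mean 0 and the
#' centred column sums of squares are attached as attribute `"sxx"`.
#'
#' @param config a [SimConfig-class].
#' @param truth the [SimTruth-class] carrying per-SNP MAFs and block ids.
#' @param seed optional replicate seed (`NULL` uses the current RNG stream).
#' @return n x (n_snps + n_extra_null) centred dosage matrix.
#' @export
genGenotypes <- function(config, truth, seed = NULL) {
  with_seed(seed, {
    m <- config@n_snps
    if (config@genotype_mode == "independent") {
      # all SNPs independent: one allocation for the whole matrix
      cpp_dosage_independent(config@n_individuals, truth@maf, TRUE)
    } else {
      G1 <- drawFocalDosages(config, truth@maf[seq_len(m)],
                             truth@block_id[seq_len(m)])
      if (config@n_extra_null > 0L) {
        G2 <- cpp_dosage_independent(config@n_individuals,
                                     truth@maf[-seq_len(m)], TRUE)
        sxx <- c(attr(G1, "sxx"), attr(G2, "sxx"))
        G <- cbind(G1, G2)
        attr(G, "sxx") <- sxx
        G
      } else G1
    }
  })
}

#' Generate a replicate's phenotypes
#'
#' Builds the covariates and outcome from the structural equations: each
#' covariate is its genetic component plus the confounder contribution plus
#' noise, and the outcome adds the direct SNP effects, the confounder, the
#' causal covariate effects and noise.
#'
#' @param G centred dosage matrix from [genGenotypes()].
#' @param truth a [SimTruth-class].
#' @param seed optional seed (`NULL` uses the current RNG stream).
#' @return list with `H` (n x p2), `Y` (length n) and the confounder `U`.
#' @export
genPhenotypes <- function(G, truth, seed = NULL) {
  with_seed(seed, {
    n <- nrow(G)
    cfg <- truth@config
    p2 <- cfg@p2
    U <- rnorm(n)
    EH <- matrix(rnorm(n * p2), n, p2) *
      rep(sqrt(diag(truth@structural@cov_EH)), each = n)
    hz <- which(rowSums(truth@beta_GH != 0) > 0)
    H <- G[, hz, drop = FALSE] %*% truth@beta_GH[hz, , drop = FALSE] +
      tcrossprod(U, truth@structural@beta_UH) + EH
    yz <- which(truth@beta_GY != 0)
    Y <- drop(G[, yz, drop = FALSE] %*% truth@beta_GY[yz]) +
      truth@structural@beta_UY * U + drop(H %*% truth@beta_HY) +
      rnorm(n, sd = sqrt(truth@var_EY))
    list(H = H, Y = Y, U = U)
  })
}

#' Run the per-replicate GWAS
#'
#' The conditional outcome GWAS regresses Y on each SNP plus all covariates
#' (exact least squares via residualisation, one matrix pass); each
#' covariate's GWAS is the marginal regression of that covariate on the SNP.
#' SNPs with zero centred variance are dropped with a message.
#'
#' @param G centred dosage matrix (attribute `"sxx"` used when present).
#' @param H n x p2 covariate matrix.
#' @param Y outcome vector.
#' @param chrom,pos,ids optional variant annotations (defaults synthesised).
#' @return An [AlignedPanel-class]: column 1 the conditional outcome effects,
#'   then the covariate effects.
#' @export
runGwas <- function(G, H, Y, chrom = NULL, pos = NULL, ids = NULL) {
  n <- nrow(G)
  m <- ncol(G)
  H <- as.matrix(H)
  p2 <- ncol(H)
  sxx <- attr(G, "sxx")
  if (is.null(sxx)) {
    G <- scale(G, center = TRUE, scale = FALSE)
    sxx <- colSums(G^2)
  }
  keep <- sxx > 0
  if (!all(keep)) {
    message(sprintf("runGwas: dropped %d constant SNPs", sum(!keep)))
    G <- G[, keep, drop = FALSE]
    sxx <- sxx[keep]
    m <- ncol(G)
  }
  Yc <- Y - mean(Y)
  Hc <- scale(H, center = TRUE, scale = FALSE)
  CP <- crossprod(G, cbind(Yc, Hc))
  gty <- CP[, 1]
  GtH <- CP[, -1, drop = FALSE]
  HtH <- crossprod(Hc)
  HtY <- drop(crossprod(Hc, Yc))
  Ci <- chol2inv(chol(HtH))
  T2 <- GtH %*% Ci
  sxx_perp <- pmax(sxx - rowSums(T2 * GtH), 0)
  sxy_perp <- gty - drop(T2 %*% HtY)
  ypy <- sum(Yc^2) - drop(t(HtY) %*% Ci %*% HtY)
  ok <- sxx_perp > 1e-10 * sxx
  beta_out <- ifelse(ok, sxy_perp / sxx_perp, 0)
  df <- n - p2 - 2L
  rss <- pmax(ypy - beta_out^2 * sxx_perp, 0)
  se_out <- ifelse(ok, sqrt(rss / df / pmax(sxx_perp, 1e-300)), Inf)
  se_out <- pmax(se_out, 1e-300)

  beta_H <- GtH / sxx
  syy <- colSums(Hc^2)
  rss_H <- pmax(rep(syy, each = m) - beta_H^2 * sxx, 0)
  se_H <- pmax(sqrt(rss_H / (n - 2L) / sxx), 1e-300)

  if (is.null(ids)) ids <- sprintf("snp%05d", seq_len(m))
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m)
  beta_out <- unname(beta_out)
  se_out <- unname(se_out)
  dimnames(beta_H) <- dimnames(se_H) <- NULL
  new("AlignedPanel", variant_ids = ids, chrom = chrom, pos = as.integer(pos),
      effect_allele = rep("A", m), other_allele = rep("G", m),
      beta = cbind(beta_out, beta_H, deparse.level = 0),
      se = cbind(se_out, se_H, deparse.level = 0),
      trait_names = c("Y_conditional", paste0("H", seq_len(p2))),
      n_vector = rep(as.integer(n), p2 + 1L))
}

alignedSubset <- function(panel, idx) {
  new("AlignedPanel", variant_ids = panel@variant_ids[idx],
      chrom = panel@chrom[idx], pos = panel@pos[idx],
      effect_allele = panel@effect_allele[idx],
      other_allele = panel@other_allele[idx],
      beta = panel@beta[idx, , drop = FALSE], se = panel@se[idx, , drop = FALSE],
      trait_names = panel@trait_names, n_vector = panel@n_vector)
}

#' Run the full simulation experiment
#'
#' With the truth fixed, each replicate draws genotypes, phenotypes and the
#' GWAS summary statistics, estimates the overlap correlation from the extra
#' null SNPs' z-scores, assembles the instrument panel, fits the requested
#' slope estimators, applies the bias correction to every focal SNP, and
#' records the per-SNP test decisions before and after correction. Fully
#' reproducible given the config seed.
#'
#' @param config a [SimConfig-class].
#' @param n_replicates number of replicates.
#' @param methods slope estimators to apply (subset of `"cml"`, `"ivw"`,
#'   `"egger"`, `"lasso"`, `"median"`).
#' @param alpha per-test significance level for the rejection-rate summaries
#'   (default 0.05).
#' @param n_starts random starts per cML fit (default 3; raise for
#'   hard problems).
#' @param perturb_B perturbation replicates for the non-cML covariances
#'   (default 200).
#' @param slope_only skip the per-SNP correction and record only the slope
#'   estimates (used for parameter-recovery studies).
#' @param progress print one line per replicate.
#' @return list with the [EvalReport-class] (`report`), per-replicate slope
#'   estimates (`slopes`), selected K per replicate (`k_hat`), rejection
#'   arrays, the truth and the config.
#' @export
runExperiment <- function(config, n_replicates, methods = "cml", alpha = 0.05,
                          n_starts = 3L, perturb_B = 200L, slope_only = FALSE,
                          progress = FALSE) {
  if (!length(methods)) stop("methods must be non-empty")
  methods <- match.arg(methods, c("cml", "ivw", "egger", "lasso", "median"),
                       several.ok = TRUE)
  truth <- drawEffects(config)
  m <- config@n_snps
  p2 <- config@p2
  focal <- seq_len(m)
  extra <- m + seq_len(config@n_extra_null)
  iv_idx <- which(truth@snp_class %in% c("iv_valid", "iv_invalid"))
  reject_before <- matrix(NA_integer_, n_replicates, m)
  reject_after <- lapply(methods, function(x) matrix(NA_integer_, n_replicates, m))
  names(reject_after) <- methods
  slopes <- list()
  k_hat <- rep(NA_integer_, n_replicates)
  se_sums <- lapply(methods, function(x) numeric(m))
  names(se_sums) <- methods
  bc_sum <- lapply(methods, function(x) numeric(m))
  names(bc_sum) <- methods
  bc_sum2 <- lapply(methods, function(x) numeric(m))
  names(bc_sum2) <- methods
  n_meth <- setNames(integer(length(methods)), methods)
  mean_se_b <- lapply(methods, function(x) matrix(NA_real_, n_replicates, p2))
  names(mean_se_b) <- methods
  bmat <- lapply(methods, function(x) matrix(NA_real_, n_replicates, p2))
  names(bmat) <- methods
  failures <- 0L

  for (r in seq_len(n_replicates)) {
    res <- tryCatch(with_seed(config@seed + r, {
      G <- genGenotypes(config, truth)
      phen <- genPhenotypes(G, truth)
      panel <- runGwas(G, phen$H, phen$Y)
      rm(G)
      corr <- suppressWarnings(
        estimateOverlapCorrelation(alignedSubset(panel, extra)))
      ivp <- new("IVPanel", iv_ids = panel@variant_ids[iv_idx],
                 beta_hat = panel@beta[iv_idx, , drop = FALSE],
                 se = panel@se[iv_idx, , drop = FALSE], sigma = list(),
                 n_min = as.integer(config@n_individuals), p2 = p2)
      ivp <- assembleSigma(ivp, corr)
      focal_panel <- alignedSubset(panel, focal)
      p_before <- 2 * pnorm(-abs(focal_panel@beta[, 1] / focal_panel@se[, 1]))
      out <- list(p_before = p_before, fits = list())
      for (meth in methods) {
        fit <- tryCatch(switch(meth,
          cml = mvmrCML(ivp, n_starts = n_starts),
          ivw = mvmrIVW(ivp),
          egger = mvmrEgger(ivp),
          lasso = mvmrLasso(ivp, B = if (slope_only) 0L else perturb_B),
          median = mvmrMedian(ivp, B = if (slope_only) 0L else perturb_B)),
          error = function(e) e)
        if (inherits(fit, "error")) {
          warning(sprintf("replicate %d, method %s failed: %s", r, meth,
                          conditionMessage(fit)))
          out$fits[[meth]] <- NULL
          next
        }
        if (meth %in% c("ivw", "egger") && !slope_only) {
          # the study design estimates non-cML slope covariances by perturbation
          fit@cov_b <- perturbCov(switch(meth, ivw = mvmrIVW, egger = mvmrEgger),
                                  ivp, B = perturb_B)
        }
        corrected <- if (slope_only) NULL else
          correctPanel(focal_panel, fit, quiet = TRUE)
        out$fits[[meth]] <- list(fit = fit, corrected = corrected)
      }
      out
    }), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      warning(sprintf("replicate %d failed and was excluded: %s", r,
                      conditionMessage(res)))
      next
    }
    reject_before[r, ] <- as.integer(res$p_before < alpha)
    for (meth in methods) {
      if (is.null(res$fits[[meth]])) next
      fit <- res$fits[[meth]]$fit
      bmat[[meth]][r, ] <- fit@b_hat
      mean_se_b[[meth]][r, ] <- sqrt(diag(fit@cov_b))
      if (meth == "cml") k_hat[r] <- fit@K_hat
      n_meth[meth] <- n_meth[meth] + 1L
      if (!slope_only) {
        cr <- res$fits[[meth]]$corrected
        reject_after[[meth]][r, ] <- as.integer(cr$pvalue < alpha)
        se_sums[[meth]] <- se_sums[[meth]] + cr$se_corrected
        bc_sum[[meth]] <- bc_sum[[meth]] + cr$beta_corrected
        bc_sum2[[meth]] <- bc_sum2[[meth]] + cr$beta_corrected^2
      }
    }
    if (progress) message(sprintf("replicate %d/%d done", r, n_replicates))
  }
  if (slope_only)
    reject_after <- setNames(vector("list", length(methods)), methods)
  results <- list(truth = truth, config = config, methods = methods,
                  alpha = alpha, reject_before = reject_before,
                  reject_after = reject_after, b = bmat, se_b = mean_se_b,
                  k_hat = k_hat, n_replicates = n_replicates,
                  n_failures = failures, n_method_fits = n_meth,
                  mean_se_corrected = if (slope_only) NULL else
                    setNames(lapply(methods, function(meth)
                      se_sums[[meth]] / n_meth[meth]), methods),
                  sd_corrected = if (slope_only) NULL else
                    setNames(lapply(methods, function(meth) {
                      R <- n_meth[meth]
                      sqrt(pmax(bc_sum2[[meth]] - bc_sum[[meth]]^2 / R, 0) /
                             max(R - 1L, 1L))
                    }), methods))
  results$report <- evaluateReplicates(results)
  results
}

classGroups <- function(cls) {
  list(null = which(cls == "null"),
       h_not_y = which(cls %in% c("h_only", "iv_valid")),
       y_only = which(cls == "y_only"),
       both = which(cls %in% c("both", "iv_invalid")))
}

#' Summarise rejection rates, power extremes and slope estimates
#'
#' Per SNP, the rejection frequency of the null hypothesis of no direct
#' effect across replicates; type-I error is averaged over SNPs whose true
#' direct effect is zero (null SNPs, and SNPs affecting the covariates
#' only), power over SNPs with a nonzero direct effect. The SNPs with the
#' greatest increase and decrease in power after correction are reported per
#' method.
#'
#' @param results the list returned by [runExperiment()].
#' @return An [EvalReport-class].
#' @export
evaluateReplicates <- function(results) {
  if (results$n_replicates - results$n_failures < 2L)
    stop("need at least 2 successful replicates")
  truth <- results$truth
  cls <- truth@snp_class[seq_len(results$config@n_snps)]
  groups <- classGroups(cls)
  rate_before <- colMeans(results$reject_before, na.rm = TRUE)
  rates <- data.frame()
  extremes <- data.frame()
  for (meth in results$methods) {
    after <- results$reject_after[[meth]]
    rate_after <- if (!is.null(after) && any(!is.na(after)))
      colMeans(after, na.rm = TRUE) else NULL
    for (g in names(groups)) {
      idx <- groups[[g]]
      if (!length(idx)) next
      rates <- rbind(rates,
        data.frame(class = g, method = "none", stage = "before",
                   rate = mean(rate_before[idx]), sd = sd(rate_before[idx]),
                   n_snps = length(idx)),
        if (!is.null(rate_after))
          data.frame(class = g, method = meth, stage = "after",
                     rate = mean(rate_after[idx]), sd = sd(rate_after[idx]),
                     n_snps = length(idx)))
    }
    if (!is.null(rate_after)) {
      nonzero <- which(truth@beta_GY[seq_along(cls)] != 0)
      delta <- rate_after[nonzero] - rate_before[nonzero]
      up <- nonzero[which.max(delta)]
      dn <- nonzero[which.min(delta)]
      extremes <- rbind(extremes,
        data.frame(method = meth, direction = c("increase", "decrease"),
                   snp = c(up, dn), class = cls[c(up, dn)],
                   power_before = rate_before[c(up, dn)],
                   power_after = rate_after[c(up, dn)]))
    }
  }
  rates <- unique(rates)
  slopes <- do.call(rbind, lapply(results$methods, function(meth) {
    ok <- which(rowSums(is.na(results$b[[meth]])) == 0)
    B <- results$b[[meth]][ok, , drop = FALSE]
    S <- results$se_b[[meth]][ok, , drop = FALSE]
    data.frame(method = meth, component = seq_len(ncol(B)),
               true_b = truth@true_b, mean_b = colMeans(B),
               sd_b = apply(B, 2, sd), mean_se = colMeans(S),
               n_fits = length(ok))
  }))
  new("EvalReport", rates = rates, extremes = extremes, slopes = slopes,
      n_replicates = sum(!is.na(results$reject_before[, 1])))
}

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport over %d replicates\n", object@n_replicates))
  cat("Rejection rates by SNP class:\n")
  print(object@rates, row.names = FALSE, digits = 3)
  if (nrow(object@extremes)) {
    cat("Power extremes:\n")
    print(object@extremes, row.names = FALSE, digits = 3)
  }
  cat("Slope estimates:\n")
  print(object@slopes, row.names = FALSE, digits = 3)
})
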