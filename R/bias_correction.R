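#' Construct a structural model
#'
#' Convenience constructor for [StructuralModel-class] with empty defaults
#' for the optional V (covariates of the covariate GWAS) and J
#' (non-heritable covariates) components.
#'
#' @param beta_UH confounder effects on the p2 heritable covariates.
#' @param beta_UY confounder effect on the outcome.
#' @param var_U confounder variance.
#' @param cov_EH covariance of the covariate noise terms (scalar, vector of
#'   variances, or full matrix).
#' @param B_VH p2 x q matrix of V effects on H (default none).
#' @param cov_V,cov_J,cov_JV covariances of V, J and their cross-covariance.
#' @param beta_HY causal effects of H on Y (default 0).
#' @param beta_JY effects of J on Y (default 0).
#' @return A [StructuralModel-class].
#' @export
structuralModel <- function(beta_UH, beta_UY, var_U, cov_EH,
                            B_VH = matrix(0, length(beta_UH), 0),
                            cov_V = matrix(0, ncol(B_VH), ncol(B_VH)),
                            cov_J = matrix(0, 0, 0),
                            cov_JV = matrix(0, nrow(cov_J), ncol(B_VH)),
                            beta_HY = rep(0, length(beta_UH)),
                            beta_JY = rep(0, nrow(cov_J))) {
  p2 <- length(beta_UH)
  if (length(cov_EH) == 1L) cov_EH <- diag(as.numeric(cov_EH), p2)
  else if (is.null(dim(cov_EH))) cov_EH <- diag(as.numeric(cov_EH), p2)
  new("StructuralModel", beta_UH = as.numeric(beta_UH),
      beta_UY = as.numeric(beta_UY), var_U = as.numeric(var_U),
      cov_EH = cov_EH, B_VH = B_VH, cov_V = cov_V, cov_J = cov_J,
      cov_JV = cov_JV, beta_HY = as.numeric(beta_HY),
      beta_JY = as.numeric(beta_JY))
}

#' Theoretical collider-bias slope
#'
#' Computes the bias slope vector b implied by the structural model: the
#' conditional (covariate-adjusted) SNP effect on the outcome equals the
#' direct effect plus `b' beta_GH`, with
#' `b = -beta_UY Var(U) M22 beta_UH` and `M22` the inverse of
#' `beta_UH beta_UH' Var(U) + Cov(E_H) + B_VH Cov(V) B_VH' -
#'  B_VH Cov(J,V)' Cov(J)^{-1} Cov(J,V) B_VH'`.
#' The V/J terms vanish when those covariate sets are empty.
#'
#' @param model a [StructuralModel-class].
#' @return Numeric bias slope vector of length p2.
#' @export
trueSlope <- function(model) {
  p2 <- length(model@beta_UH)
  M <- tcrossprod(model@beta_UH) * model@var_U + model@cov_EH
  q <- ncol(model@B_VH)
  p1 <- nrow(model@cov_J)
  if (q > 0) {
    M <- M + model@B_VH %*% model@cov_V %*% t(model@B_VH)
    if (p1 > 0 && any(model@cov_JV != 0)) {
      Jinv <- tryCatch(solve(model@cov_J), error = function(e)
        stop("Cov(J) is singular"))
      M <- M - model@B_VH %*% (t(model@cov_JV) %*% Jinv %*% model@cov_JV) %*%
        t(model@B_VH)
    }
  }
  if (rcond(M) < 1e-14) stop("singular covariance argument: M22 undefined")
  drop(-model@beta_UY * model@var_U * solve(M, model@beta_UH))
}

#' Bias-correct a single SNP
#'
#' Subtracts the estimated collider bias `b_hat' beta_GH` from the
#' conditional effect and propagates the uncertainty of the slope estimate,
#' the covariate effect estimates and the raw effect (independence form):
#' `se^2 = beta_GH' Cov(b) beta_GH + sum_k b_k^2 se_GHk^2 +
#'  sum_k Var(b_k) se_GHk^2 + se_raw^2`.
#'
#' @param beta_raw conditional outcome effect estimate.
#' @param se_raw its standard error.
#' @param beta_GH covariate effect estimates for this SNP (length p2).
#' @param se_GH their standard errors.
#' @param slope a [SlopeEstimate-class].
#' @return Named list with `beta_corrected`, `se_corrected`, `z`, `pvalue`.
#' @export
correctSnp <- function(beta_raw, se_raw, beta_GH, se_GH, slope) {
  b <- slope@b_hat
  V <- slope@cov_b
  if (length(beta_GH) != length(b)) stop("beta_GH length must equal p2")
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) stop("cov_b must be positive semidefinite")
  beta_c <- beta_raw - sum(b * beta_GH)
  var_c <- drop(t(beta_GH) %*% V %*% beta_GH) + sum(b^2 * se_GH^2) +
    sum(diag(V) * se_GH^2) + se_raw^2
  se_c <- sqrt(var_c)
  z <- beta_c / se_c
  list(beta_corrected = beta_c, se_corrected = se_c, z = z,
       pvalue = 2 * pnorm(-abs(z)))
}

#' Bias-correct an aligned panel
#'
#' Applies [correctSnp()] to every SNP of the panel and reports how many
#' SNPs are genome-wide significant before and after correction.
#'
#' @param aligned an [AlignedPanel-class].
#' @param slope a [SlopeEstimate-class].
#' @param sig_threshold significance threshold used in the summary message
#'   (default 5e-8).
#' @param quiet suppress the summary message.
#' @return data.frame of corrected records (one row per SNP) with columns
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `beta_raw`, `se_raw`, `beta_corrected`, `se_corrected`, `z`, `pvalue`.
#' @export
correctPanel <- function(aligned, slope, sig_threshold = 5e-8, quiet = FALSE) {
  b <- slope@b_hat
  V <- slope@cov_b
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) stop("cov_b must be positive semidefinite")
  X <- aligned@beta[, -1, drop = FALSE]
  SE <- aligned@se[, -1, drop = FALSE]
  beta_raw <- aligned@beta[, 1]
  se_raw <- aligned@se[, 1]
  beta_c <- beta_raw - drop(X %*% b)
  var_c <- rowSums((X %*% V) * X) + drop(SE^2 %*% (b^2 + diag(V))) + se_raw^2
  se_c <- sqrt(var_c)
  z <- beta_c / se_c
  pval <- 2 * pnorm(-abs(z))
  if (!quiet) {
    p_raw <- 2 * pnorm(-abs(beta_raw / se_raw))
    message(sprintf("correctPanel: %d of %d SNPs significant before, %d after (p < %g)",
                    sum(p_raw < sig_threshold), length(z),
                    sum(pval < sig_threshold), sig_threshold))
  }
  data.frame(variant_id = aligned@variant_ids, chrom = aligned@chrom,
             pos = aligned@pos, effect_allele = aligned@effect_allele,
             other_allele = aligned@other_allele, beta_raw = beta_raw,
             se_raw = se_raw, beta_corrected = beta_c, se_corrected = se_c,
             z = z, pvalue = pval, stringsAsFactors = FALSE)
}

#' Read a BED-like LD-block interval table
#'
#' @param path tab-separated file with columns chrom, start, end (half-open
#'   intervals, 0-based starts), no header required.
#' @return data.frame with columns `chrom`, `start`, `end`, sorted.
#' @export
readLDBlocks <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  first <- suppressWarnings(as.numeric(tab[1, 2]))
  if (is.na(first)) tab <- tab[-1, , drop = FALSE]  # tolerate a header line
  blocks <- data.frame(chrom = as.character(tab[[1]]),
                       start = as.integer(tab[[2]]), end = as.integer(tab[[3]]),
                       stringsAsFactors = FALSE)
  blocks <- blocks[order(blocks$chrom, blocks$start), ]
  rownames(blocks) <- NULL
  validateBlocks(blocks)
  blocks
}

validateBlocks <- function(blocks) {
  stopifnot(all(c("chrom", "start", "end") %in% names(blocks)))
  if (any(blocks$end <= blocks$start)) stop("blocks must have end > start")
  for (ch in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE) ||
        any(b$start[-1] < b$end[-nrow(b)]))
      stop("blocks must be sorted and non-overlapping within each chromosome")
  }
  invisible(blocks)
}

#' Count significant SNPs and loci
#'
#' Counts SNPs with corrected p-value below the threshold and the number of
#' distinct LD blocks containing at least one such SNP. Significant SNPs
#' outside every block each count as their own singleton locus (with a
#' message).
#'
#' @param records corrected records from [correctPanel()].
#' @param blocks data.frame of half-open LD-block intervals (`chrom`,
#'   `start`, `end`; 0-based starts), sorted and non-overlapping.
#' @param p_threshold significance threshold (default 5e-8).
#' @return Named list `n_sig_snps`, `n_sig_loci`.
#' @export
countLoci <- function(records, blocks, p_threshold = 5e-8) {
  validateBlocks(blocks)
  sig <- records[records$pvalue < p_threshold, , drop = FALSE]
  if (!nrow(sig)) return(list(n_sig_snps = 0L, n_sig_loci = 0L))
  hit <- character(0)
  n_outside <- 0L
  for (i in seq_len(nrow(sig))) {
    b <- blocks[blocks$chrom == sig$chrom[i], , drop = FALSE]
    pos0 <- sig$pos[i] - 1L  # 1-based position to 0-based coordinate
    k <- if (nrow(b)) findInterval(pos0, b$start) else 0L
    if (k >= 1L && pos0 < b$end[k]) {
      hit <- c(hit, sprintf("%s:%d-%d", b$chrom[k], b$start[k], b$end[k]))
    } else {
      n_outside <- n_outside + 1L
      hit <- c(hit, sprintf("singleton:%s:%d", sig$chrom[i], sig$pos[i]))
    }
  }
  if (n_outside > 0)
    message(sprintf("countLoci: %d significant SNPs outside all blocks counted as singleton loci",
                    n_outside))
  list(n_sig_snps = nrow(sig), n_sig_loci = length(unique(hit)))
}

#' Subset an IVPanel
#'
#' @param ivpanel an [IVPanel-class].
#' @param keep indices of instruments to keep.
#' @return The subset [IVPanel-class].
#' @export
ivSubset <- function(ivpanel, keep) {
  new("IVPanel", iv_ids = ivpanel@iv_ids[keep],
      beta_hat = ivpanel@beta_hat[keep, , drop = FALSE],
      se = ivpanel@se[keep, , drop = FALSE],
      sigma = if (length(ivpanel@sigma)) ivpanel@sigma[keep] else list(),
      n_min = ivpanel@n_min, p2 = ivpanel@p2)
}

#' Leave-one-instrument-out sensitivity analysis
#'
#' Refits the slope estimator l times, omitting one instrument each time,
#' and scores each instrument's influence as the Mahalanobis distance of the
#' leave-one-out slope from the full-panel slope under the full-panel
#' covariance. Instruments exceeding the upper 1% chi-squared quantile are
#' flagged as influential. Estimator failures on a leave-one-out panel are
#' recorded (NA row), not fatal.
#'
#' @param ivpanel an [IVPanel-class] with assembled `sigma`.
#' @param estimator function mapping an [IVPanel-class] to a
#'   [SlopeEstimate-class] (default [mvmrIVW()]).
#' @return data.frame with one row per instrument: the leave-one-out slope
#'   components, `influence`, and `flagged`.
#' @export
looSensitivity <- function(ivpanel, estimator = mvmrIVW) {
  l <- nrow(ivpanel@beta_hat)
  p2 <- ivpanel@p2
  if (l < p2 + 3L) stop("need at least p2 + 3 instruments for leave-one-out")
  full <- estimator(ivpanel)
  Vinv <- tryCatch(solve(full@cov_b), error = function(e)
    stop("full-panel covariance is singular"))
  out <- data.frame(iv_id = ivpanel@iv_ids,
                    matrix(NA_real_, l, p2, dimnames = list(NULL, paste0("b", seq_len(p2)))),
                    influence = NA_real_, flagged = NA, error = NA_character_,
                    stringsAsFactors = FALSE)
  cutoff <- qchisq(0.99, p2)
  for (j in seq_len(l)) {
    est <- tryCatch(estimator(ivSubset(ivpanel, setdiff(seq_len(l), j))),
                    error = function(e) e)
    if (inherits(est, "error")) {
      out$error[j] <- conditionMessage(est)
      next
    }
    d <- est@b_hat - full@b_hat
    out[j, 1 + seq_len(p2)] <- est@b_hat
    out$influence[j] <- drop(t(d) %*% Vinv %*% d)
    out$flagged[j] <- out$influence[j] > cutoff
  }
  out
}
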