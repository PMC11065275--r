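#' Greedy positional LD pruning
#'
#' Scans variants in (chrom, pos) order and keeps a variant iff its r-squared
#' with every previously kept variant on the same chromosome within the
#' trailing window of `window` SNPs is below `r2_threshold`. Deterministic
#' keep-first rule.
#'
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   sorted by (chrom, pos).
#' @param r2 either an m x m matrix of pairwise r-squared values (in variant
#'   order) or a function `(i, j)` returning the r-squared of variants `i`
#'   and `j`.
#' @param window trailing window size in SNPs (default 50).
#' @param r2_threshold exclusion threshold (default 0.001).
#' @return Character vector of kept variant ids.
#' @export
ldPrune <- function(variants, r2, window = 50L, r2_threshold = 0.001) {
  m <- nrow(variants)
  ord <- order(variants$chrom, variants$pos)
  if (!identical(ord, seq_len(m)))
    stop("variants must be sorted by (chrom, pos)")
  r2fun <- if (is.function(r2)) r2 else function(i, j) r2[i, j]
  kept <- integer(0)
  for (i in seq_len(m)) {
    cand <- kept[kept >= i - window & variants$chrom[kept] == variants$chrom[i]]
    ok <- TRUE
    for (j in rev(cand)) {
      if (r2fun(i, j) >= r2_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  variants$variant_id[kept]
}

#' Select relevant instruments from an aligned panel
#'
#' Keeps the pruned variants whose minimum covariate p-value (two-sided
#' normal from beta/se) is below `p_threshold`. The outcome column is carried
#' along. The per-IV covariance matrices are not yet assembled; see
#' [assembleSigma()].
#'
#' @param panel an [AlignedPanel-class].
#' @param pruned_ids variant ids surviving LD pruning (default: all).
#' @param p_threshold instrument relevance threshold (default 5e-10).
#' @return An [IVPanel-class] with empty `sigma`.
#' @export
selectIVs <- function(panel, pruned_ids = variantIds(panel), p_threshold = 5e-10) {
  if (p_threshold <= 0 || p_threshold > 1) stop("p_threshold must lie in (0, 1]")
  idx <- match(intersect(pruned_ids, variantIds(panel)), variantIds(panel))
  z <- abs(panel@beta[idx, -1, drop = FALSE] / panel@se[idx, -1, drop = FALSE])
  minp <- apply(2 * pnorm(-z), 1, min)
  sel <- idx[minp < p_threshold | p_threshold == 1]
  p2 <- nCovariates(panel)
  if (length(sel) < p2 + 2L)
    stop(sprintf("insufficient instruments: l = %d selected but p2 = %d requires l >= %d",
                 length(sel), p2, p2 + 2L))
  new("IVPanel", iv_ids = variantIds(panel)[sel],
      beta_hat = panel@beta[sel, , drop = FALSE],
      se = panel@se[sel, , drop = FALSE], sigma = list(),
      n_min = min(panel@n_vector), p2 = as.integer(p2))
}

nearestPSDCorrelation <- function(C, n_iter = 50L) {
  for (it in seq_len(n_iter)) {
    e <- eigen((C + t(C)) / 2, symmetric = TRUE)
    if (min(e$values) >= -1e-10) break
    C <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    d <- sqrt(pmax(diag(C), .Machine$double.eps))
    C <- C / outer(d, d)
    diag(C) <- 1
  }
  C[C > 1] <- 1; C[C < -1] <- -1
  (C + t(C)) / 2
}

#' Estimate sample-overlap correlations from null z-scores
#'
#' For each pair of traits, takes the SNPs with p-values above
#' `null_p_threshold` for both traits (null z-scores) and computes the
#' Pearson correlation of the two z-score vectors, which estimates the
#' correlation of the summary-statistic errors induced by overlapping GWAS
#' samples. Pairwise-complete estimates need not be jointly PSD, so the
#' matrix is repaired to the nearest positive semidefinite correlation.
#'
#' @param panel an [AlignedPanel-class] restricted to a designated null-SNP
#'   set (at least 200 candidates).
#' @param null_p_threshold two-sided p-value above which a SNP counts as null
#'   for a trait (default 0.1).
#' @param min_pairs minimum usable SNPs per trait pair; below it the entry is
#'   set to 0 with a warning (default 50).
#' @return An [OverlapCorrelation-class].
#' @export
estimateOverlapCorrelation <- function(panel, null_p_threshold = 0.1,
                                       min_pairs = 50L) {
  z <- panel@beta / panel@se
  if (nrow(z) < 200L)
    stop("need at least 200 candidate null SNPs, have ", nrow(z))
  p <- 2 * pnorm(-abs(z))
  nt <- ncol(z)
  C <- diag(nt)
  n_pairs <- matrix(nrow(z), nt, nt)
  for (s in seq_len(nt - 1L)) {
    for (t in (s + 1L):nt) {
      use <- p[, s] > null_p_threshold & p[, t] > null_p_threshold
      n_pairs[s, t] <- n_pairs[t, s] <- sum(use)
      if (sum(use) < min_pairs) {
        warning(sprintf("overlap correlation (%d,%d): only %d usable null SNPs; entry set to 0",
                        s, t, sum(use)))
        C[s, t] <- C[t, s] <- 0
      } else {
        C[s, t] <- C[t, s] <- cor(z[use, s], z[use, t])
      }
    }
  }
  C <- nearestPSDCorrelation(C)
  dimnames(C) <- list(panel@trait_names, panel@trait_names)
  new("OverlapCorrelation", corr = C, n_pairs = n_pairs)
}

#' Assemble per-IV covariance matrices
#'
#' Builds `Sigma_j[s, t] = corr[s, t] * se_js * se_jt` for every instrument.
#' Matrices failing a positive-definiteness check are ridge-repaired by
#' adding `1e-10 * mean(diag)` to the diagonal (with a message).
#'
#' @param x an [IVPanel-class] (its `sigma` slot is filled) or an l x (p2+1)
#'   matrix of standard errors.
#' @param corr an [OverlapCorrelation-class] or a plain correlation matrix.
#' @return The updated [IVPanel-class], or a list of covariance matrices when
#'   `x` is a matrix.
#' @export
assembleSigma <- function(x, corr) {
  C <- if (is(corr, "OverlapCorrelation")) corr@corr else corr
  ses <- if (is(x, "IVPanel")) x@se else x
  if (any(ses <= 0)) stop("all standard errors must be positive")
  if (ncol(ses) != ncol(C)) stop("correlation dimension must match the trait count")
  sig <- vector("list", nrow(ses))
  n_repaired <- 0L
  for (j in seq_len(nrow(ses))) {
    S <- unname(C * outer(ses[j, ], ses[j, ]))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12 * max(ev)) {
      S <- S + diag(1e-10 * mean(diag(S)), ncol(S))
      n_repaired <- n_repaired + 1L
    }
    sig[[j]] <- S
  }
  if (n_repaired > 0)
    message(sprintf("assembleSigma: ridge-repaired %d near-singular covariance matrices",
                    n_repaired))
  if (is(x, "IVPanel")) {
    x@sigma <- sig
    validObject(x)
    x
  } else sig
}

#' Conditional F-statistics for weak-instrument diagnosis
#'
#' Summary-data conditional instrument-strength statistic for each exposure
#' given the others. For exposure k, the other exposures' instrument effects
#' are regressed out (weighted least squares, with the delta-method residual
#' variance built from the per-IV covariance matrices), giving the
#' conditional Q-statistic `Q_k = sum_j (beta_kj - delta' beta_{-k,j})^2 /
#' var_j`, and `F_k = Q_k / (l - p2 + 1)`. For a single exposure this
#' reduces to the mean squared instrument z-score. Exposures with F below 10
#' are flagged as weak.
#'
#' @param ivpanel an [IVPanel-class] with assembled `sigma` (an identity
#'   overlap correlation is assumed if `sigma` is empty).
#' @return data.frame with columns `exposure`, `F`, `weak`.
#' @export
conditionalF <- function(ivpanel) {
  l <- nrow(ivpanel@beta_hat)
  p2 <- ivpanel@p2
  if (l <= p2) stop("need more instruments than exposures")
  bh <- ivpanel@beta_hat[, -1, drop = FALSE]
  ses <- ivpanel@se[, -1, drop = FALSE]
  sig <- ivpanel@sigma
  cov_k <- function(j) {
    if (length(sig)) sig[[j]][-1, -1, drop = FALSE]
    else diag(ses[j, ]^2, p2)
  }
  out <- data.frame(exposure = if (is.null(colnames(bh))) paste0("H", seq_len(p2))
                    else colnames(bh), F = NA_real_, weak = NA)
  for (k in seq_len(p2)) {
    if (p2 == 1L) {
      vj <- ses[, k]^2
      resid <- bh[, k]
    } else {
      X <- bh[, -k, drop = FALSE]
      w <- 1 / ses[, k]^2
      XtW <- t(X * w)
      M <- XtW %*% X
      if (rcond(M) < 1e-12)
        stop("singular instrument design across exposures: cannot compute conditional F")
      delta <- solve(M, XtW %*% bh[, k])
      # delta-method residual variance, then one reweighted pass
      for (pass in 1:2) {
        vj <- vapply(seq_len(l), function(j) {
          S <- cov_k(j)
          S[k, k] + drop(t(delta) %*% S[-k, -k, drop = FALSE] %*% delta) -
            2 * drop(S[k, -k, drop = FALSE] %*% delta)
        }, numeric(1))
        vj <- pmax(vj, 1e-12)
        if (pass == 1L) {
          w <- 1 / vj
          XtW <- t(X * w)
          delta <- solve(XtW %*% X, XtW %*% bh[, k])
        }
      }
      resid <- bh[, k] - drop(X %*% delta)
    }
    Q <- sum(resid^2 / vj)
    out$F[k] <- Q / (l - p2 + 1)
  }
  out$weak <- out$F < 10
  out
}
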