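wlsFit <- function(X, y, w) {
  XtW <- t(X * w)
  M <- XtW %*% X
  if (rcond(M) < 1e-12) stop("rank-deficient exposure matrix in weighted least squares")
  Minv <- chol2inv(chol((M + t(M)) / 2))
  coefs <- drop(Minv %*% (XtW %*% y))
  resid <- y - drop(X %*% coefs)
  list(coefs = coefs, Minv = Minv, resid = resid)
}

#' Multivariable IVW estimator of the bias slope
#'
#' Weighted least squares of the instrument-outcome effects on the
#' instrument-covariate effects without intercept, weights the inverse
#' squared outcome SEs. The covariance uses a multiplicative random-effects
#' model with the residual scale floored at 1.
#'
#' @param ivpanel an [IVPanel-class].
#' @return A [SlopeEstimate-class] with method `"ivw"`.
#' @export
mvmrIVW <- function(ivpanel) {
  X <- ivpanel@beta_hat[, -1, drop = FALSE]
  y <- ivpanel@beta_hat[, 1]
  l <- length(y)
  p2 <- ivpanel@p2
  if (l < p2 + 1L) stop("need at least p2 + 1 instruments for IVW")
  w <- 1 / ivpanel@se[, 1]^2
  fit <- wlsFit(X, y, w)
  phi <- max(1, sum(w * fit$resid^2) / max(1L, l - p2))
  new("SlopeEstimate", method = "ivw", b_hat = fit$coefs,
      cov_b = phi * fit$Minv, intercept = numeric(0),
      diagnostics = list(Q = sum(w * fit$resid^2), overdispersion = phi))
}

#' Multivariable Egger estimator (default coding)
#'
#' Instruments are reoriented so that all have positive effects on the first
#' covariate (default coding): rows with a negative first-covariate effect
#' have every beta negated. Weighted least squares with an intercept; the
#' intercept is reported as a directional-pleiotropy diagnostic.
#'
#' @param ivpanel an [IVPanel-class].
#' @return A [SlopeEstimate-class] with method `"egger"` and a nonempty
#'   `intercept`.
#' @export
mvmrEgger <- function(ivpanel) {
  B <- ivpanel@beta_hat
  l <- nrow(B)
  p2 <- ivpanel@p2
  if (l < p2 + 2L) stop("need at least p2 + 2 instruments for Egger regression")
  if (all(B[, 2] == 0))
    stop("all instrument effects on the first covariate are zero: Egger orientation undefined")
  flip <- B[, 2] < 0
  B[flip, ] <- -B[flip, ]
  X <- cbind(`(intercept)` = 1, B[, -1, drop = FALSE])
  y <- B[, 1]
  w <- 1 / ivpanel@se[, 1]^2
  fit <- wlsFit(X, y, w)
  phi <- max(1, sum(w * fit$resid^2) / max(1L, l - p2 - 1L))
  V <- phi * fit$Minv
  new("SlopeEstimate", method = "egger", b_hat = fit$coefs[-1],
      cov_b = V[-1, -1, drop = FALSE], intercept = fit$coefs[1],
      diagnostics = list(intercept_se = sqrt(V[1, 1]), overdispersion = phi,
                         n_flipped = sum(flip)))
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Multivariable MR-Lasso estimator
#'
#' The IVW model augmented with one free intercept per instrument, penalised
#' by an L1 term on the intercepts: `min_{b, a} sum_j w_j (betaY_j - a_j -
#' b' betaH_j)^2 + lambda sum_j |a_j|` with `w_j = 1/se_Yj^2`, solved by
#' alternating soft-thresholding of the intercepts and weighted least
#' squares for the slope along a descending lambda grid. The penalty is
#' chosen by the heterogeneity stopping rule: the largest lambda at which
#' the zero-intercept (valid) instruments' Q-statistic falls below the 95%
#' chi-squared quantile. The valid set is refit by IVW (post-lasso) and the
#' covariance is estimated by data perturbation.
#'
#' @param ivpanel an [IVPanel-class] with assembled `sigma` (needed for the
#'   perturbation covariance).
#' @param n_lambda grid size (default 50).
#' @param B perturbation replicates for the covariance (default 200; set to
#'   0 to skip and reuse the post-lasso IVW covariance).
#' @param seed optional seed for the perturbation.
#' @return A [SlopeEstimate-class] with method `"lasso"`.
#' @export
mvmrLasso <- function(ivpanel, n_lambda = 50L, B = 200L, seed = NULL) {
  X <- ivpanel@beta_hat[, -1, drop = FALSE]
  y <- ivpanel@beta_hat[, 1]
  l <- length(y)
  p2 <- ivpanel@p2
  if (l < p2 + 2L) stop("need at least p2 + 2 instruments for MVMR-Lasso")
  w <- 1 / ivpanel@se[, 1]^2
  ivw <- wlsFit(X, y, w)
  lam_max <- 2 * max(w * abs(ivw$resid)) * 1.0001
  if (lam_max <= 0) {
    # exact fit: every intercept is zero at any penalty
    ivw_fit <- mvmrIVW(ivpanel)
    return(new("SlopeEstimate", method = "lasso", b_hat = bHat(ivw_fit),
               cov_b = covB(ivw_fit), intercept = numeric(0),
               diagnostics = list(lambda = Inf, Q = 0, valid_set = seq_len(l))))
  }
  lambdas <- exp(seq(log(lam_max), log(lam_max * 1e-3), length.out = n_lambda))
  b <- ivw$coefs
  chosen <- NULL
  last_valid <- NULL
  for (lam in lambdas) {
    for (it in 1:200) {
      a <- soft_threshold(y - drop(X %*% b), lam / (2 * w))
      b_new <- wlsFit(X, y - a, w)$coefs
      if (max(abs(b_new - b)) < 1e-10) { b <- b_new; break }
      b <- b_new
    }
    valid <- which(a == 0)
    if (length(valid) < p2 + 2L) next
    post <- wlsFit(X[valid, , drop = FALSE], y[valid], w[valid])
    Q <- sum(w[valid] * post$resid^2)
    last_valid <- list(valid = valid, post = post, lambda = lam, Q = Q)
    if (Q <= qchisq(0.95, length(valid) - p2)) {
      chosen <- last_valid
      break
    }
  }
  if (is.null(chosen)) {
    if (is.null(last_valid))
      stop("no valid instrument set at any penalty: all intercepts nonzero")
    chosen <- last_valid
  }
  phi <- max(1, chosen$Q / max(1L, length(chosen$valid) - p2))
  est <- new("SlopeEstimate", method = "lasso", b_hat = chosen$post$coefs,
             cov_b = phi * chosen$post$Minv, intercept = numeric(0),
             diagnostics = list(lambda = chosen$lambda, Q = chosen$Q,
                                valid_set = chosen$valid))
  if (B >= 100L && length(ivpanel@sigma)) {
    est@cov_b <- perturbCov(function(p) mvmrLasso(p, n_lambda = n_lambda, B = 0L),
                            ivpanel, B = B, seed = seed)
    validObject(est)
  }
  est
}

#' Multivariable MR-median estimator
#'
#' Minimises the weighted sum of absolute residuals `sum_j |betaY_j -
#' b' betaH_j| / se_Yj` (L1 regression through the origin), solved by
#' iteratively reweighted least squares with an epsilon-smoothed weight.
#' Covariance by data perturbation.
#'
#' @param ivpanel an [IVPanel-class] (assembled `sigma` needed unless
#'   `B = 0`).
#' @param B perturbation replicates (default 200; 0 skips the perturbation
#'   and reports a crude IVW-weighted covariance).
#' @param seed optional seed for the perturbation.
#' @return A [SlopeEstimate-class] with method `"median"`.
#' @export
mvmrMedian <- function(ivpanel, B = 200L, seed = NULL) {
  X <- ivpanel@beta_hat[, -1, drop = FALSE]
  y <- ivpanel@beta_hat[, 1]
  l <- length(y)
  p2 <- ivpanel@p2
  if (l < p2 + 2L) stop("need at least p2 + 2 instruments for MVMR-median")
  w1 <- 1 / ivpanel@se[, 1]
  b <- wlsFit(X, y, w1^2)$coefs
  eps <- 1e-8
  obj <- function(b) sum(w1 * abs(y - drop(X %*% b)))
  o_old <- obj(b)
  converged <- FALSE
  for (it in 1:500) {
    resid <- y - drop(X %*% b)
    wk <- w1 / pmax(abs(resid), eps)
    b_new <- tryCatch(wlsFit(X, y, wk)$coefs, error = function(e) NULL)
    if (is.null(b_new) || !all(is.finite(b_new))) break
    o_new <- obj(b_new)
    db <- max(abs(b_new - b))
    if (o_new <= o_old + 1e-12) b <- b_new
    # stop on objective plateau or a stalled step (IRLS can oscillate within
    # machine precision around the non-smooth optimum)
    if (abs(o_new - o_old) < 1e-9 * (1 + abs(o_old)) ||
        db < 1e-9 * (1 + max(abs(b)))) { converged <- TRUE; break }
    o_old <- min(o_old, o_new)
  }
  if (!converged)
    stop("L1 (median) regression did not converge")
  fit <- wlsFit(X, y, w1^2)
  est <- new("SlopeEstimate", method = "median", b_hat = b,
             # crude IVW-shaped covariance; replaced by perturbation when B > 0
             cov_b = 1.253^2 * fit$Minv,
             intercept = numeric(0),
             diagnostics = list(iterations = it))
  if (B >= 100L && length(ivpanel@sigma)) {
    est@cov_b <- perturbCov(function(p) mvmrMedian(p, B = 0L), ivpanel,
                            B = B, seed = seed)
    validObject(est)
  }
  est
}

#' Dudbridge/Hedges-Olkin slope estimator (single covariate)
#'
#' Weighted regression through the origin of the outcome associations on the
#' covariate associations across SNPs, with the raw slope divided by the
#' Hedges-Olkin reliability ratio `1 - mean_w(se_X^2) / mean_w(betaX^2)` to
#' correct regression dilution caused by measurement error in the covariate
#' betas. Applied to all covariate-associated SNPs rather than a pruned
#' instrument set. The standard error is estimated by parametric
#' perturbation of both beta columns (independent errors unless an overlap
#' correlation is supplied).
#'
#' @param aligned an [AlignedPanel-class] with exactly one covariate.
#' @param snp_ids optional subset of variant ids to use (default: all).
#' @param corr optional 2 x 2 overlap correlation for the perturbation.
#' @param B perturbation replicates (default 200; 0 skips).
#' @param seed optional perturbation seed.
#' @return A [SlopeEstimate-class] with method `"dho"`.
#' @export
dho <- function(aligned, snp_ids = NULL, corr = NULL, B = 200L, seed = NULL) {
  if (nCovariates(aligned) != 1L) stop("dho requires exactly one covariate (p2 = 1)")
  idx <- if (is.null(snp_ids)) seq_along(aligned@variant_ids)
         else match(intersect(snp_ids, aligned@variant_ids), aligned@variant_ids)
  if (length(idx) < 50L) stop("dho needs at least 50 SNPs")
  y <- aligned@beta[idx, 1]
  x <- aligned@beta[idx, 2]
  se_y <- aligned@se[idx, 1]
  se_x <- aligned@se[idx, 2]
  w <- 1 / se_y^2
  estimate <- function(y, x) {
    raw <- sum(w * x * y) / sum(w * x^2)
    ratio <- 1 - sum(w * se_x^2) / sum(w * x^2)
    if (ratio <= 0)
      stop("Hedges-Olkin reliability ratio <= 0: covariate measurement error dominates")
    c(raw / ratio, raw, ratio)
  }
  point <- estimate(y, x)
  var_b <- (point[1] / 10)^2  # replaced by perturbation below when B > 0
  est <- new("SlopeEstimate", method = "dho", b_hat = point[1],
             cov_b = matrix(var_b, 1, 1), intercept = numeric(0),
             diagnostics = list(raw_slope = point[2], reliability = point[3],
                                n_snps = length(idx)))
  if (B >= 100L) {
    C <- if (is.null(corr)) diag(2) else corr
    cc <- chol(C)
    bs <- with_seed(seed, {
      vapply(seq_len(B), function(r) {
        E <- matrix(rnorm(2 * length(idx)), ncol = 2) %*% cc
        tryCatch(estimate(y + E[, 1] * se_y, x + E[, 2] * se_x)[1],
                 error = function(e) NA_real_)
      }, numeric(1))
    })
    if (mean(is.na(bs)) > 0.1) stop("dho perturbation failed in > 10% of replicates")
    est@cov_b <- matrix(var(bs, na.rm = TRUE), 1, 1)
    validObject(est)
  }
  est
}

#' Fit a bias-slope estimator by name
#'
#' @param ivpanel an [IVPanel-class] with assembled `sigma`.
#' @param method one of `"cml"`, `"ivw"`, `"egger"`, `"lasso"`, `"median"`.
#' @param ... passed to the underlying estimator.
#' @return A [SlopeEstimate-class] (a [CMLResult-class] for `"cml"`).
#' @export
fitSlope <- function(ivpanel, method = c("cml", "ivw", "egger", "lasso", "median"),
                     ...) {
  method <- match.arg(method)
  switch(method,
         cml = mvmrCML(ivpanel, ...),
         ivw = mvmrIVW(ivpanel),
         egger = mvmrEgger(ivpanel),
         lasso = mvmrLasso(ivpanel, ...),
         median = mvmrMedian(ivpanel, ...))
}
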