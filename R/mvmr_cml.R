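sigmaCubes <- function(ivpanel) {
  if (!length(ivpanel@sigma))
    stop("IVPanel has no assembled covariance matrices; call assembleSigma() first")
  p1 <- ivpanel@p2 + 1L
  l <- nrow(ivpanel@beta_hat)
  Sigma <- array(0, c(p1, p1, l))
  W <- array(0, c(p1, p1, l))
  for (j in seq_len(l)) {
    S <- ivpanel@sigma[[j]]
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop(sprintf("sigma[[%d]] is not positive definite", j))
    Sigma[, , j] <- S
    W[, , j] <- chol2inv(chol(S))
  }
  list(Sigma = Sigma, W = W)
}

ivwStart <- function(ivpanel) {
  X <- ivpanel@beta_hat[, -1, drop = FALSE]
  y <- ivpanel@beta_hat[, 1]
  w <- 1 / ivpanel@se[, 1]^2
  XtW <- t(X * w)
  drop(solve(XtW %*% X, XtW %*% y))
}

cmlStarts <- function(ivpanel, n_starts) {
  b0 <- ivwStart(ivpanel)
  p2 <- length(b0)
  l <- nrow(ivpanel@beta_hat)
  starts <- matrix(rep(b0, each = n_starts), n_starts, p2)
  if (n_starts > 1L) {
    extra <- n_starts - 1L
    # elemental starts: exactly-identified fits on random p2-subsets of IVs
    # (diversifies the implied valid/invalid split), then random
    # perturbations of the IVW start, alternating local and global scales
    n_elem <- extra %/% 2L
    for (i in seq_len(n_elem)) {
      idx <- sample.int(l, p2)
      be <- tryCatch(solve(ivpanel@beta_hat[idx, -1, drop = FALSE],
                           ivpanel@beta_hat[idx, 1]),
                     error = function(e) NULL)
      starts[1L + i, ] <- if (!is.null(be) && all(is.finite(be)) &&
                              max(abs(be)) < 1e6) be
        else b0 + rnorm(p2, sd = 2) * pmax(abs(b0), 0.5)
    }
    n_pert <- extra - n_elem
    if (n_pert > 0L) {
      sds <- rep(c(0.5, 2), length.out = n_pert)
      noise <- matrix(rnorm(n_pert * p2), n_pert, p2) * sds
      starts[n_elem + 1L + seq_len(n_pert), ] <-
        matrix(rep(b0, each = n_pert), n_pert, p2) +
        noise * rep(pmax(abs(b0), 0.5), each = n_pert)
    }
  }
  starts
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Constrained-ML fit with a fixed number of invalid instruments
#'
#' Maximises the summary-data Gaussian log-likelihood of the slope vector b,
#' the instrument-covariate effects and the instrument-outcome intercepts
#' under the constraint that exactly `K` intercepts are nonzero, by a
#' coordinate-descent scheme (each step an exact partial maximisation; the
#' invalid set is reset each iteration to the K instruments with the largest
#' profiled likelihood gain, ties broken by index). The best of `n_starts`
#' initialisations (multivariable IVW plus random perturbations) is kept.
#'
#' @param ivpanel an [IVPanel-class] with assembled `sigma`.
#' @param K number of invalid IVs, `0 <= K <= l - p2 - 1`.
#' @param n_starts number of initialisations (default 10).
#' @param tol convergence tolerance on the log-likelihood change (default
#'   1e-8).
#' @param max_iter iteration cap per start (default 500).
#' @param seed optional seed for the random starts.
#' @return A [CMLFitK-class].
#' @export
fitFixedK <- function(ivpanel, K, n_starts = 10L, tol = 1e-8, max_iter = 500L,
                      seed = NULL) {
  l <- nrow(ivpanel@beta_hat)
  p2 <- ivpanel@p2
  if (K < 0 || K > l - p2 - 1L)
    stop(sprintf("K must lie in [0, l - p2 - 1] = [0, %d]", l - p2 - 1L))
  cubes <- sigmaCubes(ivpanel)
  starts <- with_seed(seed, cmlStarts(ivpanel, n_starts))
  fit <- cpp_cml_fixed_k(ivpanel@beta_hat, cubes$Sigma, cubes$W, as.integer(K),
                         starts, tol, as.integer(max_iter))
  if (!fit$converged)
    warning(sprintf("coordinate descent did not converge in %d iterations (K = %d)",
                    max_iter, K))
  new("CMLFitK", K = as.integer(K), b = as.numeric(fit$b),
      betaH = fit$betaH, r = as.numeric(fit$r),
      invalid_set = as.integer(fit$invalid) + 1L, loglik = fit$loglik,
      bic = -2 * fit$loglik + K * log(ivpanel@n_min),
      converged = fit$converged,
      n_starts_agreeing = as.integer(fit$n_starts_agreeing))
}

#' MVMR-cML with BIC selection of the number of invalid instruments
#'
#' Fits the constrained maximum likelihood at every candidate K, computes
#' `BIC(K) = -2 loglik(K) + K log(N)` with N the minimum GWAS sample size,
#' and selects the K minimising BIC (ties to the smaller K). The covariance
#' of the slope estimate is the inverse observed Fisher information over the
#' selected valid instruments ([fisherCov()]).
#'
#' @param ivpanel an [IVPanel-class] with assembled `sigma`.
#' @param k_candidates candidate numbers of invalid IVs (default the full
#'   range `0:(l - p2 - 1)`).
#' @param n_starts,tol,max_iter passed to [fitFixedK()].
#' @param seed optional seed for the random starts.
#' @param warm_start also start each K from the previous K's optimum
#'   (default `TRUE`).
#' @return A [CMLResult-class].
#' @export
mvmrCML <- function(ivpanel, k_candidates = NULL, n_starts = 10L, tol = 1e-8,
                    max_iter = 500L, seed = NULL, warm_start = TRUE) {
  l <- nrow(ivpanel@beta_hat)
  p2 <- ivpanel@p2
  if (is.null(k_candidates)) k_candidates <- 0:(l - p2 - 1L)
  if (!length(k_candidates)) stop("empty candidate set for K")
  if (any(k_candidates < 0 | k_candidates > l - p2 - 1L))
    stop("k_candidates must lie within 0:(l - p2 - 1)")
  k_candidates <- sort(unique(as.integer(k_candidates)))
  cubes <- sigmaCubes(ivpanel)
  with_seed(seed, {
    per_k <- vector("list", length(k_candidates))
    prev_b <- NULL
    for (i in seq_along(k_candidates)) {
      K <- k_candidates[i]
      starts <- cmlStarts(ivpanel, n_starts)
      if (warm_start && !is.null(prev_b)) starts <- rbind(starts, prev_b)
      fit <- cpp_cml_fixed_k(ivpanel@beta_hat, cubes$Sigma, cubes$W, K,
                             starts, tol, as.integer(max_iter))
      per_k[[i]] <- new("CMLFitK", K = K, b = as.numeric(fit$b),
                        betaH = fit$betaH, r = as.numeric(fit$r),
                        invalid_set = as.integer(fit$invalid) + 1L,
                        loglik = fit$loglik,
                        bic = -2 * fit$loglik + K * log(ivpanel@n_min),
                        converged = fit$converged,
                        n_starts_agreeing = as.integer(fit$n_starts_agreeing))
      prev_b <- as.numeric(fit$b)
    }
    bics <- vapply(per_k, function(f) f@bic, numeric(1))
    K_hat <- k_candidates[which.min(bics)]  # which.min takes the first = smallest K
    sel <- per_k[[match(K_hat, k_candidates)]]
    valid <- setdiff(seq_len(l), sel@invalid_set)
    cov_b <- fisherCov(ivpanel, valid, sel@b, sel@betaH)
    new("CMLResult", method = "cml", b_hat = sel@b, cov_b = cov_b,
        intercept = numeric(0),
        diagnostics = list(bic = setNames(bics, k_candidates)),
        K_hat = as.integer(K_hat), valid_set = as.integer(valid),
        per_k = per_k, N_used = ivpanel@n_min)
  })
}

#' Observed-Fisher-information covariance of the cML slope
#'
#' Observed information of (b, instrument-covariate effects) at the
#' constrained MLE, restricted to the selected valid instruments, inverted;
#' the b-block is returned.
#'
#' @param ivpanel an [IVPanel-class] with assembled `sigma`.
#' @param valid_set 1-based indices of the valid instruments.
#' @param b_hat fitted slope vector.
#' @param beta_H fitted l x p2 instrument-covariate effect matrix.
#' @return Symmetric PSD p2 x p2 covariance matrix.
#' @export
fisherCov <- function(ivpanel, valid_set, b_hat, beta_H) {
  p2 <- ivpanel@p2
  if (length(valid_set) < p2 + 1L)
    stop("need at least p2 + 1 valid IVs for an identifiable information matrix")
  l0 <- length(valid_set)
  dim_total <- p2 + l0 * p2
  H <- matrix(0, dim_total, dim_total)
  A <- rbind(b_hat, diag(p2))
  u1 <- c(1, rep(0, p2))
  for (i in seq_along(valid_set)) {
    j <- valid_set[i]
    Wj <- chol2inv(chol(ivpanel@sigma[[j]]))
    hj <- beta_H[j, ]
    mj <- c(sum(b_hat * hj), hj)
    ej <- ivpanel@beta_hat[j, ] - mj
    idx <- p2 + (i - 1L) * p2 + seq_len(p2)
    H[seq_len(p2), seq_len(p2)] <- H[seq_len(p2), seq_len(p2)] +
      Wj[1, 1] * tcrossprod(hj)
    cross <- hj %*% (Wj[1, , drop = FALSE] %*% A) -
      drop(crossprod(ej, Wj[, 1])) * diag(p2)
    H[seq_len(p2), idx] <- cross
    H[idx, seq_len(p2)] <- t(cross)
    H[idx, idx] <- t(A) %*% Wj %*% A
  }
  if (rcond(H) < 1e-14)
    stop("singular observed information: instruments may be too weak")
  V <- solve(H)[seq_len(p2), seq_len(p2), drop = FALSE]
  (V + t(V)) / 2
}

#' Data-perturbation covariance for a slope estimator
#'
#' Parametric-bootstrap covariance: instrument effect vectors are redrawn
#' from `N(beta_hat_j, Sigma_j)`, the estimator is re-run, and the sample
#' covariance of the replicated slopes is returned.
#'
#' @param estimator function taking an [IVPanel-class] and returning either a
#'   [SlopeEstimate-class] or a numeric slope vector.
#' @param ivpanel an [IVPanel-class] with assembled `sigma`.
#' @param B number of perturbation replicates (>= 100; default 200).
#' @param seed optional seed (same seed, same output).
#' @return p2 x p2 sample covariance matrix of the perturbed slopes.
#' @export
perturbCov <- function(estimator, ivpanel, B = 200L, seed = NULL) {
  if (B < 100L) stop("B must be at least 100")
  l <- nrow(ivpanel@beta_hat)
  chols <- lapply(ivpanel@sigma, chol)
  p1 <- ivpanel@p2 + 1L
  with_seed(seed, {
    bs <- matrix(NA_real_, B, ivpanel@p2)
    n_fail <- 0L
    for (r in seq_len(B)) {
      pert <- ivpanel
      Z <- matrix(rnorm(l * p1), l, p1)
      for (j in seq_len(l))
        pert@beta_hat[j, ] <- ivpanel@beta_hat[j, ] + drop(Z[j, ] %*% chols[[j]])
      est <- tryCatch(estimator(pert), error = function(e) NULL)
      if (is.null(est)) { n_fail <- n_fail + 1L; next }
      bs[r, ] <- if (is(est, "SlopeEstimate")) est@b_hat else as.numeric(est)
    }
    if (n_fail > 0.1 * B)
      stop(sprintf("estimator failed in %d of %d perturbation replicates", n_fail, B))
    stats::cov(bs[stats::complete.cases(bs), , drop = FALSE])
  })
}

#' Brute-force global optimum of the constrained likelihood (test oracle)
#'
#' Enumerates every size-K invalid subset and, for each, maximises the
#' smooth profile likelihood over b by general-purpose numerical optimisation
#' with multiple starts; the global best is returned. Feasible only for
#' small panels (l <= 12).
#'
#' @param ivpanel an [IVPanel-class] with assembled `sigma`.
#' @param K number of invalid IVs.
#' @param n_starts optimiser starts per subset (default 5).
#' @param seed optional seed for the random starts.
#' @return A [CMLFitK-class] at the enumerated global optimum.
#' @export
cmlOracle <- function(ivpanel, K, n_starts = 5L, seed = NULL) {
  l <- nrow(ivpanel@beta_hat)
  p2 <- ivpanel@p2
  if (l > 12L) stop("cmlOracle enumeration is limited to l <= 12 instruments")
  if (K < 0 || K > l - p2 - 1L) stop("K out of range")
  bh <- ivpanel@beta_hat
  Sig <- ivpanel@sigma
  negll_subset <- function(b, valid) {
    v <- c(1, -b)
    tot <- 0
    for (j in valid) {
      denom <- drop(t(v) %*% Sig[[j]] %*% v)
      resid <- bh[j, 1] - sum(b * bh[j, -1])
      tot <- tot + resid^2 / denom
    }
    tot / 2
  }
  subsets <- if (K == 0L) list(integer(0)) else {
    cmb <- combn(l, K)
    lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  b0 <- ivwStart(ivpanel)
  with_seed(seed, {
    best <- NULL
    for (inv in subsets) {
      valid <- setdiff(seq_len(l), inv)
      starts <- rbind(b0, matrix(rep(b0, each = n_starts - 1L), n_starts - 1L, p2) +
                        matrix(rnorm((n_starts - 1L) * p2, sd = 0.5 * pmax(abs(b0), 0.5)),
                               n_starts - 1L, p2, byrow = FALSE))
      for (s in seq_len(nrow(starts))) {
        opt <- if (p2 == 1L)
          optim(starts[s, ], negll_subset, valid = valid, method = "Brent",
                lower = min(starts) - 100, upper = max(starts) + 100)
        else optim(starts[s, ], negll_subset, valid = valid, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
        if (is.null(best) || opt$value < best$value - 1e-12)
          best <- list(value = opt$value, b = opt$par, invalid = inv)
      }
    }
    b <- as.numeric(best$b)
    betaH <- matrix(0, l, p2)
    r <- numeric(l)
    A <- rbind(b, diag(p2))
    for (j in seq_len(l)) {
      if (j %in% best$invalid) {
        betaH[j, ] <- bh[j, -1]
        r[j] <- bh[j, 1] - sum(b * betaH[j, ])
      } else {
        Wj <- chol2inv(chol(Sig[[j]]))
        AtW <- t(A) %*% Wj
        betaH[j, ] <- solve(AtW %*% A, AtW %*% bh[j, ])
      }
    }
    new("CMLFitK", K = as.integer(K), b = b, betaH = betaH, r = r,
        invalid_set = as.integer(best$invalid), loglik = -best$value,
        bic = -2 * (-best$value) + K * log(ivpanel@n_min), converged = TRUE,
        n_starts_agreeing = 1L)
  })
}
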