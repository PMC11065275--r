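#' @name accessors
#' @title Accessors for colliderMR classes
#' @description Small accessor generics so downstream code never reaches into
#'   slots directly.
#' @param x an object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
#' @rdname accessors
#' @export
setGeneric("betaMatrix", function(x) standardGeneric("betaMatrix"))
#' @rdname accessors
#' @export
setGeneric("seMatrix", function(x) standardGeneric("seMatrix"))
#' @rdname accessors
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))
#' @rdname accessors
#' @export
setGeneric("nCovariates", function(x) standardGeneric("nCovariates"))
#' @rdname accessors
#' @export
setGeneric("bHat", function(x) standardGeneric("bHat"))
#' @rdname accessors
#' @export
setGeneric("covB", function(x) standardGeneric("covB"))
#' @rdname accessors
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))
#' @rdname accessors
#' @export
setGeneric("validSet", function(x) standardGeneric("validSet"))
#' @rdname accessors
#' @export
setGeneric("perKTable", function(x) standardGeneric("perKTable"))
#' @rdname accessors
#' @export
setGeneric("overlapMatrix", function(x) standardGeneric("overlapMatrix"))
#' @rdname accessors
#' @export
setGeneric("trueB", function(x) standardGeneric("trueB"))

#' @rdname accessors
#' @export
setMethod("variantIds", "TraitPanel", function(x) x@records$variant_id)
#' @rdname accessors
#' @export
setMethod("variantIds", "AlignedPanel", function(x) x@variant_ids)
#' @rdname accessors
#' @export
setMethod("variantIds", "IVPanel", function(x) x@iv_ids)
#' @rdname accessors
#' @export
setMethod("betaMatrix", "AlignedPanel", function(x) x@beta)
#' @rdname accessors
#' @export
setMethod("betaMatrix", "IVPanel", function(x) x@beta_hat)
#' @rdname accessors
#' @export
setMethod("seMatrix", "AlignedPanel", function(x) x@se)
#' @rdname accessors
#' @export
setMethod("seMatrix", "IVPanel", function(x) x@se)
#' @rdname accessors
#' @export
setMethod("traitNames", "AlignedPanel", function(x) x@trait_names)
#' @rdname accessors
#' @export
setMethod("nCovariates", "AlignedPanel", function(x) ncol(x@beta) - 1L)
#' @rdname accessors
#' @export
setMethod("nCovariates", "IVPanel", function(x) x@p2)
#' @rdname accessors
#' @export
setMethod("bHat", "SlopeEstimate", function(x) x@b_hat)
#' @rdname accessors
#' @export
setMethod("covB", "SlopeEstimate", function(x) x@cov_b)
#' @rdname accessors
#' @export
setMethod("selectedK", "CMLResult", function(x) x@K_hat)
#' @rdname accessors
#' @export
setMethod("validSet", "CMLResult", function(x) x@valid_set)
#' @rdname accessors
#' @export
setMethod("perKTable", "CMLResult", function(x) {
  do.call(rbind, lapply(x@per_k, function(f)
    data.frame(K = f@K, loglik = f@loglik, bic = f@bic, converged = f@converged,
               n_starts_agreeing = f@n_starts_agreeing)))
})
#' @rdname accessors
#' @export
setMethod("overlapMatrix", "OverlapCorrelation", function(x) x@corr)
#' @rdname accessors
#' @export
setMethod("trueB", "SimTruth", function(x) x@true_b)

setMethod("show", "TraitPanel", function(object) {
  cat(sprintf("TraitPanel '%s' (%s): %d variants, N = %d\n",
              object@trait_name, object@role, nrow(object@records),
              object@sample_size))
})

setMethod("show", "AlignedPanel", function(object) {
  cat(sprintf("AlignedPanel: %d variants x %d traits (outcome: %s; covariates: %s)\n",
              length(object@variant_ids), ncol(object@beta),
              object@trait_names[1],
              paste(object@trait_names[-1], collapse = ", ")))
})

setMethod("show", "IVPanel", function(object) {
  cat(sprintf("IVPanel: %d instruments, p2 = %d covariates, N(min) = %d\n",
              nrow(object@beta_hat), object@p2, object@n_min))
})

setMethod("show", "SlopeEstimate", function(object) {
  cat(sprintf("SlopeEstimate [%s]\n", object@method))
  se <- sqrt(diag(object@cov_b))
  tab <- data.frame(b = object@b_hat, se = se,
                    z = object@b_hat / se,
                    p = 2 * pnorm(-abs(object@b_hat / se)))
  rownames(tab) <- paste0("b", seq_along(object@b_hat))
  print(tab)
  if (length(object@intercept))
    cat(sprintf("intercept: %.4g\n", object@intercept))
})

setMethod("show", "CMLResult", function(object) {
  cat(sprintf("MVMR-cML (BIC): K_hat = %d invalid IVs, %d valid IVs, N = %d\n",
              object@K_hat, length(object@valid_set), object@N_used))
  callNextMethod()
})

setMethod("show", "OverlapCorrelation", function(object) {
  cat("OverlapCorrelation (from null z-scores):\n")
  print(round(object@corr, 3))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: n = %d, %d SNPs (+%d extra null), p2 = %d, ",
                     "%d IVs (%.0f%% invalid), rho = %.2f, %s genotypes, seed = %d\n"),
              object@n_individuals, object@n_snps, object@n_extra_null,
              object@p2, object@n_iv, 100 * object@invalid_fraction,
              object@rho, object@genotype_mode, object@seed))
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth classes:\n")
  print(table(object@snp_class))
  cat("true bias slope b:", format(object@true_b, digits = 4), "\n")
})
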