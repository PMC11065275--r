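#' Default GWAS summary-table column names
#'
#' @return Named character vector mapping the required fields to the column
#'   names expected in a tab-separated GWAS summary table.
#' @export
gwasColumns <- function() {
  c(variant_id = "SNP", chrom = "CHR", pos = "POS", effect_allele = "EA",
    other_allele = "OA", beta = "BETA", se = "SE", pvalue = "P", n = "N")
}

#' Construct a TraitPanel from a data.frame
#'
#' Rows violating the record invariants (non-positive SE, p-value outside
#' (0, 1], non-ACGT or multi-character alleles, p-value inconsistent with
#' |beta/se| under the two-sided normal approximation by more than 10% on the
#' z-scale) are dropped with a message.
#'
#' @param records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, `n`.
#' @param trait_name trait label.
#' @param role `"outcome_conditional"` or `"covariate"`.
#' @param sample_size optional trait-level sample size; rows with missing `n`
#'   fall back to it. Defaults to the maximum per-record `n`.
#' @return A [TraitPanel-class].
#' @export
traitPanel <- function(records, trait_name, role = c("covariate", "outcome_conditional"),
                       sample_size = NULL) {
  role <- match.arg(role)
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  if (!"n" %in% names(records) || all(is.na(records$n))) {
    if (is.null(sample_size))
      stop("per-record n absent: supply sample_size for trait '", trait_name, "'")
    records$n <- sample_size
  } else if (anyNA(records$n)) {
    if (is.null(sample_size)) sample_size <- max(records$n, na.rm = TRUE)
    records$n[is.na(records$n)] <- sample_size
  }
  records$n <- as.integer(records$n)
  if (!is.null(sample_size) && is.na(sample_size)) sample_size <- NULL

  # p-values below the double-precision floor are stored as 0 in many GWAS
  # tables; restore the smallest representable value when the z-score agrees
  z0 <- abs(records$beta / records$se)
  underflow <- !is.na(records$pvalue) & records$pvalue == 0 & is.finite(z0) & z0 > 37
  records$pvalue[underflow] <- .Machine$double.xmin

  keep <- !is.na(records$beta) & !is.na(records$se) & records$se > 0
  keep <- keep & !is.na(records$pvalue) & records$pvalue > 0 & records$pvalue <= 1
  keep <- keep & records$effect_allele %in% VALID_ALLELES &
    records$other_allele %in% VALID_ALLELES & records$n > 0
  # p-value vs |beta/se| consistency on the z-scale (10% relative tolerance)
  z_obs <- abs(records$beta / records$se)
  z_p <- qnorm(pmin(records$pvalue, 1) / 2, lower.tail = FALSE)
  # saturated p-values carry no more precision than "z beyond ~37"
  inconsistent <- is.finite(z_p) & z_p > 1e-8 & z_p < 37 & z_obs > 1e-8 &
    abs(z_obs - z_p) > 0.1 * pmax(z_obs, z_p)
  keep <- keep & !(inconsistent %in% TRUE)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("traitPanel('%s'): dropped %d of %d rows failing record invariants",
                    trait_name, n_drop, length(keep)))
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L)
    stop("no valid rows remain for trait '", trait_name, "'")
  if (is.null(sample_size)) sample_size <- max(records$n)
  rownames(records) <- NULL
  new("TraitPanel", trait_name = trait_name, role = role,
      records = records, sample_size = as.integer(max(sample_size, records$n)))
}

#' Read a GWAS summary table
#'
#' Reads a delimited text table with a header and validates it into a
#' [TraitPanel-class]. Rows failing the record invariants are dropped and
#' counted in a message.
#'
#' @param path file path to a tab-separated table.
#' @param trait_name trait label (defaults to the file name).
#' @param role `"covariate"` or `"outcome_conditional"`.
#' @param column_map named character vector mapping fields to column names;
#'   see [gwasColumns()]. The `n` column may be absent if `sample_size` is
#'   given.
#' @param sample_size optional trait-level sample size.
#' @param sep field separator.
#' @return A [TraitPanel-class].
#' @export
readGwasTable <- function(path, trait_name = basename(path),
                          role = c("covariate", "outcome_conditional"),
                          column_map = gwasColumns(), sample_size = NULL,
                          sep = "\t") {
  role <- match.arg(role)
  tab <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  required <- setdiff(names(gwasColumns()), if (is.null(sample_size)) character() else "n")
  missing_fields <- required[!column_map[required] %in% names(tab)]
  if (length(missing_fields))
    stop("missing required column(s) in ", path, ": ",
         paste(column_map[missing_fields], collapse = ", "))
  present <- intersect(names(column_map), names(gwasColumns()))
  present <- present[column_map[present] %in% names(tab)]
  records <- setNames(tab[column_map[present]], present)
  traitPanel(records, trait_name = trait_name, role = role,
             sample_size = sample_size)
}

#' Write a TraitPanel back to a tab-separated table
#'
#' Writes full-precision reals so that a read-back reproduces the panel.
#'
#' @param panel a [TraitPanel-class].
#' @param path output path.
#' @param column_map field-to-column mapping, see [gwasColumns()].
#' @return `path`, invisibly.
#' @export
writeGwasTable <- function(panel, path, column_map = gwasColumns()) {
  r <- panel@records
  out <- data.frame(r$variant_id, r$chrom, r$pos, r$effect_allele,
                    r$other_allele, format(r$beta, digits = 17, trim = TRUE),
                    format(r$se, digits = 17, trim = TRUE),
                    format(r$pvalue, digits = 17, trim = TRUE), r$n,
                    stringsAsFactors = FALSE)
  names(out) <- column_map[names(gwasColumns())]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Allele-harmonize an outcome panel with covariate panels
#'
#' Intersects the variants present in every panel and aligns all covariate
#' effects to the outcome panel's effect-allele orientation: where a
#' covariate record's effect/other alleles are swapped relative to the
#' outcome record the beta sign is flipped; strand-ambiguous palindromic
#' variants (A/T, C/G) are dropped by default; variants whose alleles neither
#' match nor swap are dropped.
#'
#' @param panels list of [TraitPanel-class]; the first must have role
#'   `outcome_conditional`.
#' @param drop_palindromic drop A/T and C/G variants (default `TRUE`).
#' @return An [AlignedPanel-class].
#' @export
harmonizePanels <- function(panels, drop_palindromic = TRUE) {
  if (length(panels) < 2L) stop("need the outcome panel plus >= 1 covariate panel")
  if (panels[[1]]@role != "outcome_conditional")
    stop("the first panel must have role 'outcome_conditional'")
  ids <- Reduce(intersect, lapply(panels, variantIds))
  if (!length(ids)) stop("empty variant intersection across panels")
  out <- panels[[1]]@records
  out <- out[match(ids, out$variant_id), , drop = FALSE]

  keep <- rep(TRUE, length(ids))
  if (drop_palindromic)
    keep <- keep & !is_palindromic(out$effect_allele, out$other_allele)

  p2 <- length(panels) - 1L
  beta <- matrix(NA_real_, length(ids), p2 + 1L)
  se <- matrix(NA_real_, length(ids), p2 + 1L)
  beta[, 1] <- out$beta
  se[, 1] <- out$se
  for (k in seq_len(p2)) {
    r <- panels[[k + 1L]]@records
    r <- r[match(ids, r$variant_id), , drop = FALSE]
    same <- r$effect_allele == out$effect_allele & r$other_allele == out$other_allele
    swapped <- r$effect_allele == out$other_allele & r$other_allele == out$effect_allele
    beta[, k + 1L] <- ifelse(swapped, -r$beta, r$beta)
    se[, k + 1L] <- r$se
    keep <- keep & (same | swapped)
  }
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("harmonizePanels: dropped %d of %d variants (palindromic or allele mismatch)",
                    n_drop, length(ids)))
  if (!any(keep)) stop("no variants remain after harmonization")
  new("AlignedPanel",
      variant_ids = ids[keep], chrom = out$chrom[keep], pos = out$pos[keep],
      effect_allele = out$effect_allele[keep], other_allele = out$other_allele[keep],
      beta = beta[keep, , drop = FALSE], se = se[keep, , drop = FALSE],
      trait_names = vapply(panels, function(p) p@trait_name, character(1)),
      n_vector = vapply(panels, function(p) p@sample_size, integer(1)))
}

#' Write bias-corrected summary statistics
#'
#' Writes the corrected records (as returned by [correctPanel()]) as a
#' tab-separated table with a deterministic column order and full-precision
#' reals.
#'
#' @param records data.frame of corrected records with columns `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `beta_raw`, `se_raw`,
#'   `beta_corrected`, `se_corrected`, `z`, `pvalue`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCorrected <- function(records, path) {
  if (!NROW(records)) stop("records must be non-empty")
  cols <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "beta_raw", "se_raw", "beta_corrected", "se_corrected", "z", "pvalue")
  miss <- setdiff(cols, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  out <- records[cols]
  for (nm in c("beta_raw", "se_raw", "beta_corrected", "se_corrected", "z", "pvalue"))
    out[[nm]] <- format(out[[nm]], digits = 17, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a corrected summary table
#'
#' @param path path written by [writeCorrected()].
#' @return data.frame with the corrected-record columns.
#' @export
readCorrected <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
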