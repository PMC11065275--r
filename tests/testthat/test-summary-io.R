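test_that("well-formed tables read back identically and invariant violations are dropped", {
  rec <- makeRecords(5)
  p <- traitPanel(rec, "bmi", role = "covariate")
  expect_s4_class(p, "TraitPanel")
  expect_equal(nrow(p@records), 5L)

  rec_bad <- rec
  rec_bad$se[3] <- 0
  expect_message(p2 <- traitPanel(rec_bad, "bmi"), "dropped 1 of 5")
  expect_equal(nrow(p2@records), 4L)
  expect_false("rs0003" %in% variantIds(p2))

  # p-value inconsistent with beta/se on the z-scale is dropped too
  rec_bad2 <- rec
  rec_bad2$pvalue[1] <- 2 * pnorm(-abs(rec$beta[1] / rec$se[1]) * 2)
  expect_message(p3 <- traitPanel(rec_bad2, "bmi"), "dropped 1")
  expect_equal(nrow(p3@records), 4L)
})

test_that("read(write(panel)) round-trips a random 100-record panel", {
  p <- traitPanel(makeRecords(100, seed = 42), "whr", role = "outcome_conditional")
  path <- tempfile(fileext = ".tsv")
  writeGwasTable(p, path)
  p2 <- readGwasTable(path, trait_name = "whr", role = "outcome_conditional")
  expect_equal(p2@records$beta, p@records$beta, tolerance = 1e-12)
  expect_equal(p2@records$se, p@records$se, tolerance = 1e-12)
  expect_equal(p2@records$pvalue, p@records$pvalue, tolerance = 1e-12)
  expect_identical(variantIds(p2), variantIds(p))
  unlink(path)
})

test_that("readGwasTable rejects missing columns and empty results", {
  p <- traitPanel(makeRecords(5), "x")
  path <- tempfile(fileext = ".tsv")
  writeGwasTable(p, path)
  tab <- read.delim(path)
  tab$BETA <- NULL
  path2 <- tempfile(fileext = ".tsv")
  write.table(tab, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readGwasTable(path2), "missing required column")
  unlink(c(path, path2))
})

test_that("harmonization flips swapped alleles, drops palindromes and mismatches", {
  out_rec <- makeRecords(6, seed = 3)
  out_rec$effect_allele <- c("A", "C", "A", "G", "C", "A")
  out_rec$other_allele <- c("G", "T", "T", "C", "A", "C")  # rs3 A/T, rs4 G/C palindromic
  cov_rec <- out_rec
  cov_rec$beta <- c(0.3, -0.2, 0.1, 0.4, 0.5, -0.1)
  # swap rs1's alleles in the covariate panel
  cov_rec <- flipRecords(cov_rec, 1)
  cov_rec$beta[1] <- 0.3  # beta as reported under the swapped coding
  # rs6: allele mismatch
  cov_rec$other_allele[6] <- "G"
  cov_rec$pvalue <- 2 * pnorm(-abs(cov_rec$beta / cov_rec$se))
  out_rec$pvalue <- 2 * pnorm(-abs(out_rec$beta / out_rec$se))
  outp <- traitPanel(out_rec, "y", role = "outcome_conditional")
  covp <- traitPanel(cov_rec, "h")
  suppressMessages(al <- harmonizePanels(list(outp, covp)))
  expect_setequal(variantIds(al), c("rs0001", "rs0002", "rs0005"))
  expect_equal(al@beta[match("rs0001", variantIds(al)), 2], -0.3)
  expect_equal(al@beta[match("rs0002", variantIds(al)), 2], -0.2)
})

test_that("harmonization is idempotent and invariant to recoding a covariate panel", {
  out <- traitPanel(makeRecords(50, seed = 7), "y", role = "outcome_conditional")
  cov_rec <- makeRecords(50, seed = 8)
  covp <- traitPanel(cov_rec, "h")
  suppressMessages(al1 <- harmonizePanels(list(out, covp)))
  # recode every record of the covariate panel: swap alleles, negate beta
  covp_flip <- traitPanel(flipRecords(cov_rec), "h")
  suppressMessages(al2 <- harmonizePanels(list(out, covp_flip)))
  expect_equal(al2@beta, al1@beta)
  expect_identical(variantIds(al2), variantIds(al1))
  # idempotence on the induced panels
  induced_out <- traitPanel(data.frame(
    variant_id = al1@variant_ids, chrom = al1@chrom, pos = al1@pos,
    effect_allele = al1@effect_allele, other_allele = al1@other_allele,
    beta = al1@beta[, 1], se = al1@se[, 1],
    pvalue = 2 * pnorm(-abs(al1@beta[, 1] / al1@se[, 1])), n = 10000L),
    "y", role = "outcome_conditional")
  induced_cov <- traitPanel(data.frame(
    variant_id = al1@variant_ids, chrom = al1@chrom, pos = al1@pos,
    effect_allele = al1@effect_allele, other_allele = al1@other_allele,
    beta = al1@beta[, 2], se = al1@se[, 2],
    pvalue = 2 * pnorm(-abs(al1@beta[, 2] / al1@se[, 2])), n = 10000L), "h")
  suppressMessages(al3 <- harmonizePanels(list(induced_out, induced_cov)))
  expect_equal(al3@beta, al1@beta)
})

test_that("harmonization errors on empty intersections", {
  out <- traitPanel(makeRecords(5, seed = 1), "y", role = "outcome_conditional")
  cov_rec <- makeRecords(5, seed = 2)
  cov_rec$variant_id <- paste0("other", 1:5)
  covp <- traitPanel(cov_rec, "h")
  expect_error(harmonizePanels(list(out, covp)), "empty")
  expect_error(harmonizePanels(list(covp, out)), "outcome_conditional")
})

test_that("corrected records write and read back at full precision", {
  rec <- data.frame(variant_id = "rs1", chrom = "1", pos = 100L,
                    effect_allele = "A", other_allele = "G",
                    beta_raw = 1 / 3, se_raw = 0.3, beta_corrected = 0.8,
                    se_corrected = sqrt(0.102), z = 0.8 / sqrt(0.102),
                    pvalue = 2 * pnorm(-0.8 / sqrt(0.102)))
  path <- tempfile(fileext = ".tsv")
  writeCorrected(rec, path)
  expect_equal(length(readLines(path)), 2L)
  back <- readCorrected(path)
  for (nm in c("beta_raw", "se_raw", "beta_corrected", "se_corrected", "z", "pvalue"))
    expect_equal(back[[nm]], rec[[nm]], tolerance = 1e-12)
  unlink(path)
  expect_error(writeCorrected(rec[0, ], tempfile()), "non-empty")
})
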