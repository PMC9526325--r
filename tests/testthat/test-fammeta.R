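# Fam-meta: relative records, the relatives' regression, and the
# kinship-weighted inverse-variance combination.

.mkResult <- function(beta, variance, converged = TRUE) {
  new("AssociationResult", beta = beta, variance = variance,
      statistic = beta / sqrt(variance),
      pvalue = 2 * pnorm(-abs(beta / sqrt(variance))), n = 100,
      converged = converged)
}

test_that("relative records count parents and grandparents correctly", {
  st <- fixtureStudy()
  rec <- buildRelativeRecords(st$cohort, st$genotypes, st$phenotypes,
                              "snp4", "parents")
  expect_equal(nrow(rec), 800L)
  expect_true(all(rec$phi == 0.25))
  expect_true(all(rec$proband_genotype_mean >= 0 &
                    rec$proband_genotype_mean <= 2))
  expect_true(all(rec$proband_phenotype_mean >= 0 &
                    rec$proband_phenotype_mean <= 1))
  expect_error(buildRelativeRecords(st$cohort, st$genotypes,
                                    st$phenotypes, "snp4",
                                    "four_grandparents"),
               "three-generation")

  st3 <- simulateStudy("causal_model", mode = "three_generation", seed = 8)
  rec4 <- buildRelativeRecords(st3$cohort, st3$genotypes, st3$phenotypes,
                               "snp4", "four_grandparents")
  expect_equal(nrow(rec4), 1600L)
  expect_true(all(rec4$phi == 0.125))
  rec2 <- buildRelativeRecords(st3$cohort, st3$genotypes, st3$phenotypes,
                               "snp4", "two_grandparents", seed = 9)
  expect_equal(nrow(rec2), 800L)
  # one full grandparent pair per family, never a mixed pair
  m <- members(st3$cohort)
  side <- sub("_.*$", "", sub("^grand(father|mother)_", "",
                              m$role[match(rec2$relative_id,
                                           m$individual_id)]))
  fam <- m$family_id[match(rec2$relative_id, m$individual_id)]
  expect_true(all(tapply(side, fam, function(s) length(unique(s))) == 1))
  expect_true(all(tapply(side, fam, length) == 2))
  expect_error(buildRelativeRecords(st3$cohort, st3$genotypes,
                                    st3$phenotypes, "snp4", "parents"),
               "nuclear")
})

test_that("the meta combination evaluates the kinship-weighted formula", {
  r0 <- combineMeta(.mkResult(0, 1), .mkResult(0, 2), 0.25)
  expect_equal(r0@tMeta, 0)
  r1 <- combineMeta(.mkResult(1, 1), .mkResult(1, 1), 0.25)
  expect_equal(r1@tMeta, 1.5 / sqrt(1.25), tolerance = 1e-12)  # 1.3416
  # uninformative relative stream: reduces to the proband z
  r2 <- combineMeta(.mkResult(0.4, 0.01), .mkResult(1, 1e12), 0.25)
  expect_equal(r2@tMeta, 0.4 / sqrt(0.01), tolerance = 1e-4)
  # symmetric when phi = 0.5 and variances are equal
  r3 <- combineMeta(.mkResult(0.7, 2), .mkResult(-0.2, 2), 0.5)
  r4 <- combineMeta(.mkResult(-0.2, 2), .mkResult(0.7, 2), 0.5)
  expect_equal(r3@tMeta, r4@tMeta, tolerance = 1e-12)
  # monotone in both effects
  base <- combineMeta(.mkResult(0.2, 1), .mkResult(0.1, 1), 0.25)@tMeta
  expect_gt(combineMeta(.mkResult(0.3, 1), .mkResult(0.1, 1), 0.25)@tMeta,
            base)
  expect_gt(combineMeta(.mkResult(0.2, 1), .mkResult(0.2, 1), 0.25)@tMeta,
            base)
  expect_error(combineMeta(.mkResult(1, 0), .mkResult(1, 1), 0.25),
               "variance")
  # non-converged inputs propagate as a flagged result
  rbad <- combineMeta(.mkResult(1, 1), .mkResult(NA_real_, NA_real_,
                                                 converged = FALSE), 0.25)
  expect_false(rbad@converged)
  expect_true(is.na(rbad@pvalue))
})

test_that("the relatives' regression rejects degenerate inputs and is
           null-calibrated under permutation", {
  st <- fixtureStudy()
  rec <- buildRelativeRecords(st$cohort, st$genotypes, st$phenotypes,
                              "snp6", "parents")
  res <- relativeTest(rec)
  expect_true(res@converged)
  expect_equal(res@n, 800)

  recBad <- rec
  recBad$relative_status <- 0L
  expect_error(relativeTest(recBad), "class")

  # permuting relative statuses against proband genotypes gives a
  # nominal-level test
  set.seed(50)
  p <- replicate(300, {
    r <- rec
    r$relative_status <- sample(r$relative_status)
    relativeTest(r)@pvalue
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 300) + 0.01)
})

test_that("fammetaTest combines the two streams for each relative role", {
  st <- fixtureStudy()
  res <- fammetaTest(st$cohort, st$genotypes, st$phenotypes, "snp8")
  expect_s4_class(res, "MetaResult")
  expect_true(res@converged)
  expect_equal(res@phi, 0.25)
  # the proband stream is exactly CC-GWAS
  cc <- ccgwasTest(st$cohort, st$genotypes, st$phenotypes, "snp8")
  expect_equal(res@proband@beta, cc@beta)
  expect_equal(res@pvalue, 2 * pnorm(-abs(res@tMeta)))

  st3 <- simulateStudy("causal_model", mode = "three_generation", seed = 8)
  res4 <- fammetaTest(st3$cohort, st3$genotypes, st3$phenotypes, "snp8",
                      relativeRole = "four_grandparents")
  expect_equal(res4@phi, 0.125)
  expect_true(res4@converged)
})
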