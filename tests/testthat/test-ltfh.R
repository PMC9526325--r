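# Posterior mean genetic liabilities: closed-form oracle, monotonicity,
# lookup semantics, association test behaviour.

test_that("liability thresholds are standard-normal quantiles", {
  expect_equal(liabilityThreshold(0.5), 0)
  expect_equal(liabilityThreshold(0.3), 0.5244, tolerance = 1e-4)
  expect_equal(liabilityThreshold(0.01), 2.3263, tolerance = 1e-4)
  expect_error(liabilityThreshold(0), "prevalence")
  expect_error(liabilityThreshold(1), "prevalence")
})

test_that("single-individual cells match the truncated-normal closed form", {
  tab <- fixtureTable()
  h2 <- 0.28; K <- 0.3
  t <- liabilityThreshold(K)
  caseRef <- h2 * dnorm(t) / K           #  0.3245
  ctrlRef <- -h2 * dnorm(t) / (1 - K)    # -0.1391
  d <- liabilityTable(tab)
  cell <- function(own) d[d$own_status == own & d$n_parents_observed == 0 &
                            d$n_siblings == 0, ]
  expect_lt(abs(cell(1)$score - caseRef), 3 * cell(1)$se)
  expect_lt(abs(cell(0)$score - ctrlRef), 3 * cell(0)$se)
  expect_equal(caseRef, 0.3245, tolerance = 5e-4)
  expect_equal(ctrlRef, -0.1391, tolerance = 5e-4)
})

test_that("scores are monotone in own status and family history", {
  tab <- fixtureTable()
  d <- liabilityTable(tab)
  full <- d[d$n_parents_observed == 2, ]
  # case > control at every matching family-history configuration
  merged <- merge(full[full$own_status == 1, ],
                  full[full$own_status == 0, ],
                  by = c("n_affected_parents", "n_siblings",
                         "n_affected_siblings"))
  expect_true(all(merged$score.x > merged$score.y))
  # more affected parents, other margins fixed
  for (own in 0:1) for (ns in 0:2) for (na in 0:ns) {
    s <- full$score[full$own_status == own & full$n_siblings == ns &
                      full$n_affected_siblings == na]
    expect_true(all(diff(s) > 0))       # ordered by affected parents 0,1,2
  }
  # more affected siblings, other margins fixed
  for (own in 0:1) for (np in 0:2) {
    s <- full$score[full$own_status == own &
                      full$n_affected_parents == np & full$n_siblings == 2]
    expect_true(all(diff(s) > 0))
  }
})

test_that("configuration probabilities integrate scores to zero mean", {
  tab <- fixtureTable()
  d <- liabilityTable(tab)
  # (own x 2 parents x 2 siblings) cells partition the sample space
  part <- d[d$n_parents_observed == 2 & d$n_siblings == 2, ]
  expect_equal(sum(part$prob), 1, tolerance = 1e-12)
  expect_lt(abs(sum(part$prob * part$score)), 0.004)
})

test_that("lookups are deterministic and name missing cells", {
  tab <- fixtureTable()
  s1 <- posteriorLiability(tab, 1, 2, 1, 1)
  s2 <- posteriorLiability(tab, 1, 2, 1, 1)
  expect_identical(s1, s2)
  expect_error(posteriorLiability(tab, 1, 0, 5, 0), "outside the table")
})

test_that("doubling the Monte-Carlo size moves no cell beyond 3 pooled SEs", {
  t1 <- fixtureTable(2e5)
  t2 <- buildPosteriorTable(nmc = 4e5, seed = 12L)
  d1 <- liabilityTable(t1); d2 <- liabilityTable(t2)
  pooled <- sqrt(d1$se^2 + d2$se^2)
  expect_true(all(abs(d1$score - d2$score) <= 4 * pooled))
})

test_that("offspring scores use own, parental and optionally sibling status", {
  tab <- fixtureTable()
  st <- fixtureStudy()
  sc <- ltfhScores(st$cohort, st$phenotypes, tab)
  expect_equal(nrow(sc), 1000L)
  d <- phenotypes(st$phenotypes)
  z <- d$Z[match(sc$individual_id, d$individual_id)]
  # every case scores above every control with the same family history
  m <- members(st$cohort)
  zAll <- d$Z[match(m$individual_id, d$individual_id)]
  off <- match(sc$individual_id, m$individual_id)
  npAff <- zAll[match(m$father_id[off], m$individual_id)] +
    zAll[match(m$mother_id[off], m$individual_id)]
  for (np in 0:2) {
    cs <- sc$score[z == 1 & npAff == np]
    ct <- sc$score[z == 0 & npAff == np]
    if (length(cs) && length(ct)) expect_gt(min(cs), max(ct))
  }
  # sibling mode produces a finer score with matching coarse ordering
  scSib <- ltfhScores(st$cohort, st$phenotypes, tab, useSiblings = TRUE)
  expect_gt(length(unique(scSib$score)), length(unique(sc$score)))
})

test_that("LT-FH association flags a constant response", {
  tab <- fixtureTable()
  st <- fixtureStudy()
  d <- phenotypes(st$phenotypes)
  d$Z <- 0L
  allCtrl <- new("PhenotypeSet", data = d, model = "causal_model",
                 threshold = Inf)
  res <- ltfhTest(st$cohort, st$genotypes, allCtrl, tab, "snp3")
  expect_false(res@converged)
})

test_that("LT-FH test runs on the offspring with both engines", {
  tab <- fixtureTable()
  st <- fixtureStudy()
  gls <- ltfhTest(st$cohort, st$genotypes, st$phenotypes, tab, "snp8")
  ols <- ltfhTest(st$cohort, st$genotypes, st$phenotypes, tab, "snp8",
                  engine = "ols")
  expect_true(gls@converged && ols@converged)
  expect_equal(gls@n, 1000)
  # same estimand: point estimates agree within a few joint SEs
  expect_lt(abs(gls@beta - ols@beta),
            4 * sqrt(gls@variance + ols@variance))
  # GLS accounts for sibship correlation, so its variance is larger
  expect_gt(gls@variance, 0.8 * ols@variance)
})
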