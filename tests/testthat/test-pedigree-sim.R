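# Family-structure generation, founder genotypes, gene dropping, kinship.

test_that("nuclear and three-generation cohorts have the documented sizes", {
  coh <- generateCohort(200, 200, seed = 1)
  expect_equal(nIndividuals(coh), 1800L)
  expect_equal(nFamilies(coh), 400L)
  expect_equal(length(offspringIds(coh)), 1000L)

  coh3 <- generateThreeGenerationCohort(200, 200, seed = 1)
  expect_equal(nIndividuals(coh3), 3400L)
  expect_equal(sum(startsWith(members(coh3)$role, "grand")), 1600L)

  expect_equal(nIndividuals(generateCohort(0, 0, seed = 1)), 0L)
  one <- generateThreeGenerationCohort(1, 0, seed = 2)
  expect_equal(nIndividuals(one), 8L)
  expect_equal(sum(startsWith(members(one)$role, "grand")), 4L)
})

test_that("every generated family satisfies the age rules (exhaustive scan)", {
  for (coh in list(generateCohort(600, 400, seed = 3),
                   generateThreeGenerationCohort(100, 100, seed = 4))) {
    m <- members(coh)
    off <- m[m$role == "offspring", ]
    expect_true(all(off$age >= 18 & off$age <= 45))
    # scan every couple against the age of their oldest child (member rows
    # are id-ordered, so per-role extraction follows ascending family id)
    kidAge <- as.numeric(tapply(off$age, off$family_id, max))
    fa <- m$age[m$role == "father"]
    mo <- m$age[m$role == "mother"]
    expect_true(all(mo - kidAge >= 20 & mo - kidAge <= 45))
    expect_true(all(abs(fa - mo) <= 5))
    expect_true(all(fa - kidAge >= 20))
    if (cohortMode(coh) == "three_generation") {
      # grandparent couples obey the same rules one generation up
      for (side in c("paternal", "maternal")) {
        parent <- if (side == "paternal") "father" else "mother"
        pAge <- m$age[m$role == parent]
        gm <- m$age[m$role == paste0("grandmother_", side)]
        gf <- m$age[m$role == paste0("grandfather_", side)]
        expect_true(all(gm - pAge >= 20 & gm - pAge <= 45))
        expect_true(all(abs(gf - gm) <= 5))
        expect_true(all(gf - pAge >= 20))
      }
    }
  }
})

test_that("offspring sex is random while parental sexes are fixed by role", {
  m <- members(generateCohort(500, 500, seed = 6))
  expect_true(all(m$sex[m$role == "father"] == 0L))
  expect_true(all(m$sex[m$role == "mother"] == 1L))
  pFemale <- mean(m$sex[m$role == "offspring"])
  expect_lt(abs(pFemale - 0.5), 3 * sqrt(0.25 / 2500))
})

test_that("founder genotypes follow Hardy-Weinberg at the requested MAF", {
  coh <- generateCohort(2000, 2000, seed = 7)   # 8000 founders
  founders <- founderIds(coh)
  gt <- drawFounderGenotypes(c(0.1, 0.5), founders, seed = 8)
  G <- genotypes(gt)
  n <- length(founders)
  # empirical allele frequency within 3 binomial SEs
  expect_lt(abs(mean(G[, 1]) / 2 - 0.1), 3 * sqrt(0.1 * 0.9 / (2 * n)))
  # symmetric case: genotype class frequencies near (1/4, 1/2, 1/4)
  freq <- tabulate(G[, 2] + 1L, 3L) / n
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 0.02))
  expect_error(drawFounderGenotypes(0, founders), "MAF")
  expect_error(drawFounderGenotypes(0.6, founders), "MAF")
})

test_that("gene dropping obeys Mendelian transmission", {
  coh <- fixtureQuartet()
  # homozygous parents force heterozygous children
  gt <- geneDrop(coh, fixtureFounderGeno(2, 0), seed = 1)
  expect_equal(unname(genotypes(gt)[c("3", "4"), 1]), c(1L, 1L))
  # two heterozygous parents: offspring genotypes (1/4, 1/2, 1/4)
  set.seed(20)
  draws <- replicate(4000,
    genotypes(geneDrop(coh, fixtureFounderGeno(1, 1)))["3", 1])
  freq <- tabulate(draws + 1L, 3L) / 4000
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 0.035))
})

test_that("allele frequency is conserved across generations", {
  coh <- generateThreeGenerationCohort(300, 300, seed = 9)
  gt <- drawFounderGenotypes(c(0.05, 0.3), founderIds(coh), seed = 10)
  all <- geneDrop(coh, gt, seed = 11)
  m <- members(coh)
  for (gen in 1:2) {
    rows <- as.character(m$individual_id[m$generation == gen])
    G <- genotypes(all)[rows, ]
    n <- length(rows)
    expect_lt(abs(mean(G[, 1]) / 2 - 0.05), 3 * sqrt(0.05 * 0.95 / (2 * n)))
    expect_lt(abs(mean(G[, 2]) / 2 - 0.30), 4 * sqrt(0.30 * 0.70 / (2 * n)))
  }
})

test_that("kinship matrices carry the canonical coefficients and are PSD", {
  coh <- generateThreeGenerationCohort(1, 0, seed = 12)
  phi <- kinshipMatrix(coh, 1)
  m <- members(coh)
  id <- function(role) as.character(m$individual_id[m$role == role][1])
  expect_true(isSymmetric(phi))
  expect_true(all(diag(phi) == 0.5))
  expect_equal(phi[id("father"), id("offspring")], 0.25)
  expect_equal(phi[id("father"), id("mother")], 0)
  expect_equal(phi[id("grandfather_paternal"), id("offspring")], 0.125)
  expect_equal(phi[id("grandfather_paternal"), id("grandfather_maternal")], 0)
  kids <- as.character(m$individual_id[m$role == "offspring"])
  expect_equal(phi[kids[1], kids[2]], 0.25)
  expect_true(all(eigen(phi, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
})

test_that("kinship equals half the expected IBD sharing (Monte-Carlo oracle)", {
  # independent allele-label dropping oracle at one locus
  coh <- generateThreeGenerationCohort(1, 0, seed = 13)
  m <- members(coh)
  n <- nrow(m)
  fa <- match(m$father_id, m$individual_id)
  mo <- match(m$mother_id, m$individual_id)
  ord <- order(m$generation)
  set.seed(14)
  reps <- 4000
  acc <- matrix(0, n, n)
  for (r in seq_len(reps)) {
    lab <- matrix(NA_integer_, n, 2)
    nxt <- 1L
    for (i in ord) {
      if (is.na(fa[i])) {
        lab[i, ] <- c(nxt, nxt + 1L); nxt <- nxt + 2L
      } else {
        lab[i, 1] <- lab[fa[i], sample.int(2, 1)]
        lab[i, 2] <- lab[mo[i], sample.int(2, 1)]
      }
    }
    # P(randomly drawn alleles are IBD), averaged over the 4 allele pairs
    for (i in seq_len(n)) for (j in i:n) {
      s <- (outer(lab[i, ], lab[j, ], "==") * 1)
      if (i == j) diag(s) <- 1
      acc[i, j] <- acc[i, j] + mean(s)
    }
  }
  est <- acc / reps
  phi <- kinshipMatrix(coh, 1)
  idx <- match(rownames(phi), as.character(m$individual_id))
  for (a in seq_len(n)) for (b in a:n)
    expect_lt(abs(est[idx[a], idx[b]] - phi[a, b]), 0.03)
})

test_that("identical seeds reproduce cohorts and genotypes bit for bit", {
  c1 <- generateCohort(50, 50, seed = 15)
  c2 <- generateCohort(50, 50, seed = 15)
  expect_identical(members(c1), members(c2))
  g1 <- drawFounderGenotypes(0.2, founderIds(c1), seed = 16)
  g2 <- drawFounderGenotypes(0.2, founderIds(c2), seed = 16)
  expect_identical(genotypes(geneDrop(c1, g1, seed = 17)),
                   genotypes(geneDrop(c2, g2, seed = 17)))
})
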