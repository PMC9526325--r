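# Shared fixtures, built once per test run. The posterior table is the
# slowest piece (~0.5 s at 2e5 draws), so it is cached in an environment.

.fixtures <- new.env(parent = emptyenv())

fixtureTable <- function(nmc = 2e5) {
  key <- paste0("tab", nmc)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- buildPosteriorTable(h2 = 0.28, prevalence = 0.3,
                                            nmc = nmc, maxSiblings = 2L,
                                            seed = 11L)
  .fixtures[[key]]
}

fixtureStudy <- function() {
  if (is.null(.fixtures$study))
    .fixtures$study <- simulateStudy("causal_model", seed = 5L)
  .fixtures$study
}

# tiny hand-built one-family cohort: father 1, mother 2, offspring 3, 4
fixtureQuartet <- function() {
  m <- data.frame(
    individual_id = 1:4, family_id = 1L,
    father_id = c(NA, NA, 1L, 1L), mother_id = c(NA, NA, 2L, 2L),
    role = c("father", "mother", "offspring", "offspring"),
    sex = c(0L, 1L, 0L, 1L), age = c(62, 60, 30, 25),
    generation = c(0L, 0L, 1L, 1L), stringsAsFactors = FALSE)
  new("FamCohort", members = m, mode = "nuclear")
}

# GenotypeTable for the quartet's founders with fixed parental codes
fixtureFounderGeno <- function(gFather, gMother, maf = 0.25) {
  g <- matrix(as.integer(c(gFather, gMother)), ncol = 1,
              dimnames = list(c("1", "2"), "snp1"))
  new("GenotypeTable", geno = g,
      variants = data.frame(variant_id = "snp1", maf = maf))
}
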