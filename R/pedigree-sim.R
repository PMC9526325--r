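# Pedigree simulation: family structures, founder genotypes under HWE,
# gene dropping, and exact kinship matrices.

.checkCount <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != round(x))
    stop(sprintf("'%s' must be a single non-negative integer", name),
         call. = FALSE)
  as.integer(x)
}

.maybeSeed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Derive independent sub-seeds from a master seed (one per replicate or
# stage) without consuming the caller's stream beyond one set.seed().
.spawnSeeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

# Ages for a couple given the age of their oldest child: the mother is
# 20-45 years older than the oldest child, the father is within 5 years of
# the mother and at least 20 years older than the oldest child.
.coupleAges <- function(oldestChildAge) {
  n <- length(oldestChildAge)
  mother <- oldestChildAge + runif(n, 20, 45)
  lo <- pmax(-5, 20 - (mother - oldestChildAge))
  father <- mother + lo + runif(n) * (5 - lo)
  cbind(father = father, mother = mother)
}

.emptyMembers <- function() {
  data.frame(individual_id = integer(), family_id = integer(),
             father_id = integer(), mother_id = integer(),
             role = character(), sex = integer(), age = numeric(),
             generation = integer(), stringsAsFactors = FALSE)
}

#' Generate a cohort of nuclear families
#'
#' Simulates `nTwoChild` families with two offspring and `nThreeChild`
#' families with three offspring. Offspring ages are uniform on \[18, 45\]
#' years and offspring sex is assigned uniformly at random; the mother is
#' 20-45 years older than her oldest child, and the father is within five
#' years of the mother's age and at least 20 years older than the oldest
#' child. The default 200 + 200 families give a cohort of 1800 individuals
#' with 1000 offspring.
#'
#' @param nTwoChild number of two-offspring families.
#' @param nThreeChild number of three-offspring families.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return a [FamCohort-class] in `"nuclear"` mode.
#' @examples
#' coh <- generateCohort(200, 200, seed = 1)
#' nIndividuals(coh)  # 1800
#' @export
generateCohort <- function(nTwoChild = 200, nThreeChild = 200, seed = NULL) {
  n2 <- .checkCount(nTwoChild, "nTwoChild")
  n3 <- .checkCount(nThreeChild, "nThreeChild")
  .maybeSeed(seed)
  nfam <- n2 + n3
  if (nfam == 0L)
    return(new("FamCohort", members = .emptyMembers(), mode = "nuclear"))

  k <- rep(c(2L, 3L), c(n2, n3))              # offspring per family
  famSize <- 2L + k
  start <- cumsum(c(0L, famSize[-nfam]))      # id offset per family

  kidFam <- rep(seq_len(nfam), k)
  kidAge <- runif(sum(k), 18, 45)
  oldest <- vapply(split(kidAge, kidFam), max, numeric(1))
  couple <- .coupleAges(oldest)

  fatherId <- start + 1L
  motherId <- start + 2L
  kidWithin <- sequence(k)
  kidId <- start[kidFam] + 2L + kidWithin

  m <- data.frame(
    individual_id = c(fatherId, motherId, kidId),
    family_id     = c(seq_len(nfam), seq_len(nfam), kidFam),
    father_id     = c(rep(NA_integer_, 2L * nfam), fatherId[kidFam]),
    mother_id     = c(rep(NA_integer_, 2L * nfam), motherId[kidFam]),
    role          = c(rep("father", nfam), rep("mother", nfam),
                      rep("offspring", sum(k))),
    sex           = c(rep(0L, nfam), rep(1L, nfam),
                      rbinom(sum(k), 1L, 0.5)),
    age           = c(couple[, "father"], couple[, "mother"], kidAge),
    generation    = c(rep(0L, 2L * nfam), rep(1L, sum(k))),
    stringsAsFactors = FALSE)
  m <- m[order(m$individual_id), , drop = FALSE]
  rownames(m) <- NULL
  new("FamCohort", members = m, mode = "nuclear")
}

#' Generate a cohort of three-generation families
#'
#' Same topology as [generateCohort()] with, in addition, both parents of
#' each parent (four grandparents per family). Grandparent ages apply the
#' couple rules one generation up: each grandmother is 20-45 years older
#' than her child (the parent), each grandfather within five years of the
#' grandmother and at least 20 years older than that parent. The default
#' 200 + 200 families give 3400 individuals with 1000 grandchildren.
#'
#' @inheritParams generateCohort
#' @return a [FamCohort-class] in `"three_generation"` mode.
#' @export
generateThreeGenerationCohort <- function(nTwoChild = 200, nThreeChild = 200,
                                          seed = NULL) {
  n2 <- .checkCount(nTwoChild, "nTwoChild")
  n3 <- .checkCount(nThreeChild, "nThreeChild")
  .maybeSeed(seed)
  nfam <- n2 + n3
  if (nfam == 0L)
    return(new("FamCohort", members = .emptyMembers(),
               mode = "three_generation"))

  k <- rep(c(2L, 3L), c(n2, n3))
  famSize <- 6L + k                            # 4 grandparents + 2 parents + k
  start <- cumsum(c(0L, famSize[-nfam]))

  kidFam <- rep(seq_len(nfam), k)
  kidAge <- runif(sum(k), 18, 45)
  oldest <- vapply(split(kidAge, kidFam), max, numeric(1))
  parents <- .coupleAges(oldest)
  gpPat <- .coupleAges(parents[, "father"])    # father's parents
  gpMat <- .coupleAges(parents[, "mother"])    # mother's parents

  gfPatId <- start + 1L; gmPatId <- start + 2L
  gfMatId <- start + 3L; gmMatId <- start + 4L
  fatherId <- start + 5L; motherId <- start + 6L
  kidId <- start[kidFam] + 6L + sequence(k)

  fid <- seq_len(nfam)
  m <- data.frame(
    individual_id = c(gfPatId, gmPatId, gfMatId, gmMatId,
                      fatherId, motherId, kidId),
    family_id     = c(rep(fid, 4L), fid, fid, kidFam),
    father_id     = c(rep(NA_integer_, 4L * nfam),
                      gfPatId, gfMatId, fatherId[kidFam]),
    mother_id     = c(rep(NA_integer_, 4L * nfam),
                      gmPatId, gmMatId, motherId[kidFam]),
    role          = c(rep("grandfather_paternal", nfam),
                      rep("grandmother_paternal", nfam),
                      rep("grandfather_maternal", nfam),
                      rep("grandmother_maternal", nfam),
                      rep("father", nfam), rep("mother", nfam),
                      rep("offspring", sum(k))),
    sex           = c(rep(c(0L, 1L, 0L, 1L), each = nfam),
                      rep(0L, nfam), rep(1L, nfam),
                      rbinom(sum(k), 1L, 0.5)),
    age           = c(gpPat[, "father"], gpPat[, "mother"],
                      gpMat[, "father"], gpMat[, "mother"],
                      parents[, "father"], parents[, "mother"], kidAge),
    generation    = c(rep(0L, 4L * nfam), rep(1L, 2L * nfam),
                      rep(2L, sum(k))),
    stringsAsFactors = FALSE)
  m <- m[order(m$individual_id), , drop = FALSE]
  rownames(m) <- NULL
  new("FamCohort", members = m, mode = "three_generation")
}

#' Founder individuals of a cohort
#'
#' Founders are the members without in-pedigree parents: the parents in
#' nuclear mode, the grandparents in three-generation mode.
#'
#' @param cohort a [FamCohort-class].
#' @return integer vector of founder individual ids.
#' @export
founderIds <- function(cohort) {
  m <- members(cohort)
  m$individual_id[is.na(m$father_id)]
}

#' Draw founder genotypes under Hardy-Weinberg equilibrium
#'
#' For each variant, founder minor-allele counts are i.i.d. Binomial(2, MAF),
#' i.e. P(2 minor alleles) = MAF^2, P(1) = 2 MAF (1 - MAF),
#' P(0) = (1 - MAF)^2.
#'
#' @param mafs numeric vector of minor-allele frequencies, each in (0, 0.5\].
#' @param founders vector of founder individual ids.
#' @param seed optional integer seed.
#' @param variantIds optional variant names (default `snp1`, `snp2`, ...).
#' @return a [GenotypeTable-class] with one row per founder.
#' @export
drawFounderGenotypes <- function(mafs, founders, seed = NULL,
                                 variantIds = NULL) {
  if (!length(mafs) || any(!is.finite(mafs)) ||
      any(mafs <= 0 | mafs > 0.5))
    stop("all MAFs must lie in (0, 0.5]", call. = FALSE)
  .maybeSeed(seed)
  if (is.null(variantIds)) variantIds <- paste0("snp", seq_along(mafs))
  n <- length(founders)
  g <- vapply(mafs, function(p) rbinom(n, 2L, p), integer(n))
  if (n == 1L) g <- matrix(g, nrow = 1L)
  dimnames(g) <- list(as.character(founders), variantIds)
  new("GenotypeTable", geno = g,
      variants = data.frame(variant_id = variantIds, maf = mafs,
                            stringsAsFactors = FALSE))
}

# One transmitted allele per (parent, variant): homozygotes transmit their
# allele, heterozygotes a fair coin.
.transmit <- function(G) {
  (G == 2L) + (G == 1L) * matrix(rbinom(length(G), 1L, 0.5), nrow(G))
}

#' Gene-drop genotypes through a cohort's pedigrees
#'
#' Propagates founder genotypes to all descendants by Mendelian transmission:
#' each parent passes one of their two alleles with equal probability. In
#' three-generation mode the parents are gene-dropped from the grandparents
#' before the offspring.
#'
#' @param cohort a [FamCohort-class].
#' @param founderGenotypes a [GenotypeTable-class] covering every founder of
#'   the cohort.
#' @param seed optional integer seed.
#' @return a [GenotypeTable-class] with one row per cohort member.
#' @export
geneDrop <- function(cohort, founderGenotypes, seed = NULL) {
  m <- members(cohort)
  fg <- genotypes(founderGenotypes)
  founders <- founderIds(cohort)
  if (!all(as.character(founders) %in% rownames(fg)))
    stop("founder genotypes missing for some founders", call. = FALSE)
  .maybeSeed(seed)
  nv <- ncol(fg)
  G <- matrix(NA_integer_, nrow(m), nv,
              dimnames = list(as.character(m$individual_id), colnames(fg)))
  G[as.character(founders), ] <- fg[as.character(founders), , drop = FALSE]
  for (g in sort(unique(m$generation[!is.na(m$father_id)]))) {
    idx <- which(m$generation == g & !is.na(m$father_id))
    if (!length(idx)) next
    pf <- G[as.character(m$father_id[idx]), , drop = FALSE]
    pm <- G[as.character(m$mother_id[idx]), , drop = FALSE]
    if (anyNA(pf) || anyNA(pm))
      stop("parents lack genotypes before their children; invalid pedigree",
           call. = FALSE)
    G[idx, ] <- .transmit(pf) + .transmit(pm)
  }
  new("GenotypeTable", geno = G, variants = variantInfo(founderGenotypes))
}

# Recursive kinship for a single non-inbred-founder pedigree given the
# member rows of one family (parents precede children by generation).
.kinshipFromPed <- function(fam) {
  fam <- fam[order(fam$generation, fam$individual_id), , drop = FALSE]
  n <- nrow(fam)
  ids <- fam$individual_id
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  pos <- setNames(seq_len(n), ids)
  for (i in seq_len(n)) {
    if (is.na(fam$father_id[i])) {
      phi[i, i] <- 0.5
    } else {
      f <- pos[[as.character(fam$father_id[i])]]
      mo <- pos[[as.character(fam$mother_id[i])]]
      phi[i, i] <- 0.5 * (1 + phi[f, mo])
      for (j in seq_len(i - 1L))
        phi[i, j] <- phi[j, i] <- 0.5 * (phi[f, j] + phi[mo, j])
    }
  }
  phi
}

#' Kinship matrix of one family
#'
#' Exact kinship coefficients from the pedigree: diagonal 0.5, parent to
#' offspring and full siblings 0.25, grandparent to grandchild 0.125,
#' spouses 0 (founders are unrelated and non-inbred).
#'
#' @param cohort a [FamCohort-class].
#' @param familyId the family to extract.
#' @return symmetric matrix of kinship coefficients indexed by individual id.
#' @export
kinshipMatrix <- function(cohort, familyId) {
  m <- members(cohort)
  fam <- m[m$family_id == familyId, , drop = FALSE]
  if (!nrow(fam)) stop("no such family: ", familyId, call. = FALSE)
  .kinshipFromPed(fam)
}
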