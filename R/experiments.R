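# Replicate engines for type-I-error and power studies. A cohort template
# (pedigree topology, row indices, Cholesky factors of the family
# relationship matrices) is precomputed once per experiment; each replicate
# redraws ages, sexes, genotypes, polygenic values and errors, then runs
# the requested association tests on every tested variant.

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' @param successes number of successes (0..`trials`).
#' @param trials number of trials.
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(low, high)`.
#' @examples
#' exactBinomCI(5, 100)  # 0.0164 .. 0.1128
#' @export
exactBinomCI <- function(successes, trials, level = 0.95) {
  if (length(successes) != 1L || length(trials) != 1L ||
      is.na(successes) || is.na(trials) ||
      successes < 0 || trials < 0 || successes > trials)
    stop("need 0 <= successes <= trials", call. = FALSE)
  a <- 1 - level
  low <- if (successes == 0) 0 else qbeta(a / 2, successes,
                                          trials - successes + 1)
  high <- if (successes == trials) 1 else qbeta(1 - a / 2, successes + 1,
                                                trials - successes)
  c(low = low, high = high)
}

#' Genomic-control inflation factor
#'
#' The median of the 1-df chi-square statistics implied by two-sided
#' p-values, divided by the null 1-df chi-square median (0.4549).
#'
#' @param pvalues vector of p-values in (0, 1\].
#' @return numeric inflation factor.
#' @export
lambdaGC <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (!length(pvalues)) stop("no p-values supplied", call. = FALSE)
  if (any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  chi <- qchisq(pvalues, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}

# ---------------------------------------------------------------------------
# cohort template: everything about the study design that does not change
# across replicates

.cohortTemplate <- function(nTwoChild = 200, nThreeChild = 200,
                            mode = c("nuclear", "three_generation")) {
  mode <- match.arg(mode)
  coh <- if (mode == "nuclear")
    generateCohort(nTwoChild, nThreeChild, seed = 1L)
  else generateThreeGenerationCohort(nTwoChild, nThreeChild, seed = 1L)
  m <- members(coh)
  n <- nrow(m)
  nfam <- length(unique(m$family_id))

  kidRows <- which(m$role == "offspring")
  fatherRowKid <- match(m$father_id[kidRows], m$individual_id)
  motherRowKid <- match(m$mother_id[kidRows], m$individual_id)
  famOfKid <- m$family_id[kidRows]
  kidSplit <- split(seq_along(kidRows), famOfKid)
  famN <- lengths(kidSplit)[as.character(seq_len(nfam))]

  founderRows <- which(is.na(m$father_id))
  drops <- list()
  for (g in sort(unique(m$generation[!is.na(m$father_id)]))) {
    rows <- which(m$generation == g & !is.na(m$father_id))
    drops[[length(drops) + 1L]] <-
      list(rows = rows, fa = match(m$father_id[rows], m$individual_id),
           mo = match(m$mother_id[rows], m$individual_id))
  }

  famSize <- table(m$family_id)
  groups <- list()
  for (sz in unique(as.integer(famSize))) {
    fids <- sort(as.integer(names(famSize)[famSize == sz]))
    phi <- .kinshipFromPed(m[m$family_id == fids[1L], , drop = FALSE])
    groups[[length(groups) + 1L]] <-
      list(rows = which(m$family_id %in% fids), sz = sz,
           nf = length(fids), L = chol(2 * phi))
  }

  fatherRows <- which(m$role == "father")
  motherRows <- which(m$role == "mother")
  parentRows <- sort(c(fatherRows, motherRows))
  parentFam <- m$family_id[parentRows]

  gpRows <- patRows <- matRows <- NULL
  if (mode == "three_generation") {
    gpRows <- which(startsWith(m$role, "grand"))
    patRows <- cbind(which(m$role == "grandfather_paternal"),
                     which(m$role == "grandmother_paternal"))
    matRows <- cbind(which(m$role == "grandfather_maternal"),
                     which(m$role == "grandmother_maternal"))
  }

  list(mode = mode, m = m, n = n, nfam = nfam,
       kidRows = kidRows, nKid = length(kidRows),
       fatherRowKid = fatherRowKid, motherRowKid = motherRowKid,
       famOfKid = famOfKid, kidSplit = kidSplit, famN = as.integer(famN),
       founderRows = founderRows, drops = drops, groups = groups,
       fatherRows = fatherRows, motherRows = motherRows,
       parentRows = parentRows, parentFam = parentFam,
       gpRows = gpRows, gpFam = if (!is.null(gpRows)) m$family_id[gpRows],
       patRows = patRows, matRows = matRows,
       sexFixed = m$sex, role = m$role)
}

# redraw ages and offspring sexes in place
.drawAgesSexes <- function(tpl) {
  age <- numeric(tpl$n)
  kidAge <- runif(tpl$nKid, 18, 45)
  age[tpl$kidRows] <- kidAge
  oldest <- vapply(tpl$kidSplit, function(ii) max(kidAge[ii]), numeric(1))
  oldest <- oldest[as.character(seq_len(tpl$nfam))]
  couple <- .coupleAges(oldest)
  age[tpl$fatherRows] <- couple[, "father"]
  age[tpl$motherRows] <- couple[, "mother"]
  if (tpl$mode == "three_generation") {
    gpPat <- .coupleAges(couple[, "father"])
    gpMat <- .coupleAges(couple[, "mother"])
    age[tpl$patRows[, 1L]] <- gpPat[, "father"]
    age[tpl$patRows[, 2L]] <- gpPat[, "mother"]
    age[tpl$matRows[, 1L]] <- gpMat[, "father"]
    age[tpl$matRows[, 2L]] <- gpMat[, "mother"]
  }
  sex <- tpl$sexFixed
  sex[tpl$kidRows] <- rbinom(tpl$nKid, 1L, 0.5)
  list(age = age, sex = sex)
}

# founder HWE draw + gene dropping for all variants at once
.drawGenotypes <- function(tpl, mafs) {
  nv <- length(mafs)
  nf <- length(tpl$founderRows)
  G <- matrix(0L, tpl$n, nv)
  G[tpl$founderRows, ] <- rbinom(nf * nv, 2L, rep(mafs, each = nf))
  for (d in tpl$drops)
    G[d$rows, ] <- .transmit(G[d$fa, , drop = FALSE]) +
      .transmit(G[d$mo, , drop = FALSE])
  G
}

.drawPolygenic <- function(tpl, sigmaG2) {
  out <- numeric(tpl$n)
  if (sigmaG2 == 0) return(out)
  s <- sqrt(sigmaG2)
  for (g in tpl$groups)
    out[g$rows] <- as.vector(crossprod(g$L, matrix(rnorm(g$sz * g$nf),
                                                   g$sz, g$nf))) * s
  out
}

# posterior-liability lookup array indexed by
# [own+1, affected parents+1, siblings+1, affected siblings+1]
.ltfhScoreArray <- function(tableObj, maxSiblings = 2L) {
  tab <- liabilityTable(tableObj)
  tab <- tab[tab$n_parents_observed == 2L &
               tab$n_siblings <= maxSiblings, , drop = FALSE]
  arr <- array(NA_real_, c(2L, 3L, maxSiblings + 1L, maxSiblings + 1L))
  arr[cbind(tab$own_status + 1L, tab$n_affected_parents + 1L,
            tab$n_siblings + 1L, tab$n_affected_siblings + 1L)] <- tab$score
  arr
}

# one full simulate-and-test replicate; returns p-values and convergence
# per (tested variant x analysis stream)
.replicateOnce <- function(tpl, model, cfg, testCols, streams, scoreArr,
                           allMafs, useSiblings = FALSE) {
  stage <- sample.int(2147483646L, 5L)

  set.seed(stage[1L]); as1 <- .drawAgesSexes(tpl)
  set.seed(stage[2L]); G <- .drawGenotypes(tpl, allMafs)
  set.seed(stage[3L]); gamma <- .drawPolygenic(tpl, cfg$sigmaG2)
  set.seed(stage[4L]); err <- rnorm(tpl$n, 0, sqrt(cfg$sigmaE2))

  age <- as1$age; sex <- as1$sex
  snp <- numeric(tpl$n)
  if (model != "null_model") {
    betas <- effectSize(cfg$mafs, cfg$pvePerSnp)
    snp <- as.vector(G[, seq_along(cfg$mafs), drop = FALSE] %*% betas)
  }
  Y <- snp + cfg$ageCoef * age + cfg$sexCoef * sex + gamma + err
  if (model == "interaction_model")
    Y <- Y + cfg$interactionAgeCoef * age * snp

  k <- as.integer(round(tpl$n * cfg$prevalence))
  Z <- integer(tpl$n)
  Z[order(-Y, tpl$m$individual_id)[seq_len(k)]] <- 1L

  zKid <- Z[tpl$kidRows]
  ageKid <- age[tpl$kidRows]; sexKid <- sex[tpl$kidRows]
  famIdxKid <- tpl$famOfKid

  ltfhY <- NULL
  if ("ltfh" %in% streams) {
    famAff <- as.integer(
      rowsum(zKid, famIdxKid)[as.character(seq_len(tpl$nfam)), 1L])
    nSib <- tpl$famN[famIdxKid] - 1L
    nAffSib <- famAff[famIdxKid] - zKid
    if (!useSiblings) { nSib <- nSib * 0L; nAffSib <- nAffSib * 0L }
    npAff <- Z[tpl$fatherRowKid] + Z[tpl$motherRowKid]
    ltfhY <- scoreArr[cbind(zKid + 1L, npAff + 1L, nSib + 1L, nAffSib + 1L)]
  }

  relStreams <- streams[startsWith(streams, "fammeta")]
  relSetup <- list()
  if (length(relStreams)) {
    set.seed(stage[5L])
    for (rs in relStreams) {
      role <- sub("^fammeta_", "", rs)
      if (role == "parents") {
        rows <- tpl$parentRows; famIdx <- tpl$parentFam; phi <- 0.25
      } else if (role == "four_grandparents") {
        rows <- tpl$gpRows; famIdx <- tpl$gpFam; phi <- 0.125
      } else {
        sel <- runif(tpl$nfam) < 0.5
        pick <- tpl$patRows
        pick[!sel, ] <- tpl$matRows[!sel, ]
        rows <- as.vector(pick)
        famIdx <- rep(seq_len(tpl$nfam), 2L)
        phi <- 0.125
      }
      relSetup[[rs]] <- list(rows = rows, famIdx = famIdx, phi = phi,
                             z = Z[rows], age = age[rows], sex = sex[rows])
    }
    zMeanFam <- as.vector(
      rowsum(zKid, famIdxKid)[as.character(seq_len(tpl$nfam)), 1L]) /
      tpl$famN
  }

  nT <- length(testCols)
  pv <- matrix(NA_real_, nT, length(streams),
               dimnames = list(NULL, streams))
  for (j in seq_len(nT)) {
    g <- G[, testCols[j]]
    gKid <- g[tpl$kidRows]
    Xoff <- cbind(1, gKid, ageKid, sexKid)
    cc <- NULL
    if ("ccgwas" %in% streams || length(relStreams)) {
      cc <- .logisticFitGEE(zKid, Xoff, cluster = famIdxKid)
      if ("ccgwas" %in% streams && cc$converged)
        pv[j, "ccgwas"] <- cc$pvalue
    }
    if ("ltfh" %in% streams) {
      lf <- .linearFitGLS(ltfhY, Xoff, cluster = famIdxKid)
      if (lf$converged) pv[j, "ltfh"] <- lf$pvalue
    }
    if (length(relStreams)) {
      gMeanFam <- as.vector(
        rowsum(gKid, famIdxKid)[as.character(seq_len(tpl$nfam)), 1L]) /
        tpl$famN
      for (rs in relStreams) {
        st <- relSetup[[rs]]
        Xrel <- cbind(1, gMeanFam[st$famIdx], zMeanFam[st$famIdx],
                      st$age, st$sex)
        rr <- .logisticFit(st$z, Xrel)
        if (cc$converged && rr$converged) {
          t <- (cc$beta / cc$variance +
                  2 * st$phi * rr$beta / rr$variance) /
            sqrt(1 / cc$variance + 4 * st$phi^2 / rr$variance)
          pv[j, rs] <- 2 * pnorm(-abs(t))
        }
      }
    }
  }
  pv
}

# shared driver: returns p-value array [replicate, tested variant, stream]
.runReplicates <- function(model, mode, cfg, testMafs, streams,
                           nReplicates, seed, ltfhTable = NULL,
                           nullVariants = FALSE, useSiblings = FALSE,
                           nTwoChild = 200, nThreeChild = 200) {
  tpl <- .cohortTemplate(nTwoChild, nThreeChild, mode)
  if (is.null(testMafs)) testMafs <- cfg$mafs
  if (nullVariants && model == "null_model") {
    # no causal variants needed: the phenotype ignores genotypes entirely
    allMafs <- testMafs
    testCols <- seq_along(testMafs)
  } else if (nullVariants) {
    allMafs <- c(cfg$mafs, testMafs)
    testCols <- length(cfg$mafs) + seq_along(testMafs)
  } else {
    allMafs <- cfg$mafs
    testCols <- match(testMafs, cfg$mafs)
    if (anyNA(testCols))
      stop("tested MAFs must be among the model's causal MAFs",
           call. = FALSE)
  }
  scoreArr <- NULL
  if ("ltfh" %in% streams) {
    if (is.null(ltfhTable))
      ltfhTable <- buildPosteriorTable(h2 = 0.28,
                                       prevalence = cfg$prevalence,
                                       nmc = 1e6, maxSiblings = 2L,
                                       seed = seed)
    scoreArr <- .ltfhScoreArray(ltfhTable, maxSiblings = 2L)
  }
  repSeeds <- .spawnSeeds(seed, nReplicates)
  pv <- array(NA_real_, c(nReplicates, length(testCols), length(streams)),
              dimnames = list(NULL, paste0("maf", testMafs), streams))
  for (r in seq_len(nReplicates)) {
    set.seed(repSeeds[r])
    pv[r, , ] <- .replicateOnce(tpl, model, cfg, testCols, streams,
                                scoreArr, allMafs,
                                useSiblings = useSiblings)
  }
  list(pvals = pv, testMafs = testMafs, streams = streams)
}

.tabulate <- function(res, alphas, nReplicates, level = 0.95) {
  out <- list()
  for (a in alphas) {
    rej <- apply(res$pvals < a, c(2, 3), sum, na.rm = TRUE)
    nonconv <- apply(is.na(res$pvals), c(2, 3), sum)
    for (s in res$streams) for (i in seq_along(res$testMafs)) {
      ci <- exactBinomCI(rej[i, s], nReplicates, level)
      out[[length(out) + 1L]] <- data.frame(
        maf = res$testMafs[i], method = s, alpha = a,
        power = rej[i, s] / nReplicates,
        ci_low = ci[["low"]], ci_high = ci[["high"]],
        n_nonconverged = nonconv[i, s], n_replicates = nReplicates)
    }
  }
  tab <- do.call(rbind, out)
  # increase over the CC-GWAS baseline, cell by cell
  tab$increase_over_ccgwas <- NA_real_
  if ("ccgwas" %in% res$streams) {
    base <- tab[tab$method == "ccgwas", ]
    key <- paste(tab$maf, tab$alpha)
    bkey <- paste(base$maf, base$alpha)
    tab$increase_over_ccgwas <- tab$power - base$power[match(key, bkey)]
    tab$increase_over_ccgwas[tab$method == "ccgwas"] <- NA_real_
  }
  rownames(tab) <- NULL
  # per-replicate p-values kept for paired comparisons between cells
  attr(tab, "pvals") <- res$pvals
  tab
}

.methodStreams <- function(methods, relativeRole = "parents") {
  streams <- character()
  if ("ccgwas" %in% methods) streams <- c(streams, "ccgwas")
  if ("ltfh" %in% methods) streams <- c(streams, "ltfh")
  if ("fammeta" %in% methods)
    streams <- c(streams, paste0("fammeta_", relativeRole))
  streams
}

#' Type-I-error study under a chosen phenotype model
#'
#' Per replicate, simulates a nuclear cohort and its phenotype, draws eight
#' additional non-causal variants with the same allele frequencies
#' independently of the phenotype, tests each with the requested methods,
#' and tabulates rejection proportions at each alpha with exact binomial
#' 95% confidence intervals. Non-converged fits count as non-rejections
#' and are reported in `n_nonconverged`.
#'
#' @param model phenotype model (default `"null_model"`).
#' @param methods subset of `c("ccgwas", "ltfh", "fammeta")`.
#' @param nReplicates number of replicates.
#' @param alphas nominal levels (default 0.05, 0.01, 0.005).
#' @param mafs allele frequencies of the tested null variants.
#' @param seed master seed; every replicate derives its own sub-seeds.
#' @param ltfhTable optional prebuilt [PosteriorLiabilityTable-class]
#'   (built automatically when LT-FH is requested).
#' @param config optional [phenotypeModelConfig()] override.
#' @return data.frame with one row per (maf, method, alpha): rejection
#'   rate (`power` column), exact binomial CI, non-convergence count.
#' @export
runType1 <- function(model = "null_model",
                     methods = c("ccgwas", "ltfh", "fammeta"),
                     nReplicates = 1000, alphas = c(0.05, 0.01, 0.005),
                     mafs = NULL, seed = 1L, ltfhTable = NULL,
                     config = NULL) {
  cfg <- if (is.null(config)) phenotypeModelConfig(model) else config
  if (is.null(mafs)) mafs <- cfg$mafs
  streams <- .methodStreams(methods)
  res <- .runReplicates(cfg$model, "nuclear", cfg, mafs, streams,
                        nReplicates, seed, ltfhTable = ltfhTable,
                        nullVariants = TRUE)
  .tabulate(res, alphas, nReplicates)
}

#' Power study under the causal or interaction model
#'
#' Per replicate, simulates a nuclear cohort with the eight causal variants
#' entering the phenotype, tests the causal variants with the requested
#' methods at level `alpha`, and tabulates power with exact binomial 95%
#' confidence intervals and the increase over the CC-GWAS baseline.
#'
#' @inheritParams runType1
#' @param model `"causal_model"` or `"interaction_model"`.
#' @param alpha nominal level (default 0.05).
#' @param testMafs subset of the causal MAFs to test (default all eight).
#' @export
runPower <- function(model = c("causal_model", "interaction_model"),
                     methods = c("ccgwas", "ltfh", "fammeta"),
                     nReplicates = 5000, alpha = 0.05, testMafs = NULL,
                     seed = 1L, ltfhTable = NULL, config = NULL) {
  model <- match.arg(model)
  cfg <- if (is.null(config)) phenotypeModelConfig(model) else config
  streams <- .methodStreams(methods)
  res <- .runReplicates(cfg$model, "nuclear", cfg, testMafs, streams,
                        nReplicates, seed, ltfhTable = ltfhTable)
  .tabulate(res, alpha, nReplicates)
}

#' Grandparent-scenario power study
#'
#' Three-generation cohorts under the causal model: CC-GWAS on the
#' grandchildren (n = 1000) and Fam-meta using either all four grandparents
#' (n = 1600 relatives) or one randomly selected grandparent pair per
#' family (n = 800 relatives) as the family-history source.
#'
#' @inheritParams runPower
#' @export
runGrandparentPower <- function(nReplicates = 5000, alpha = 0.05,
                                testMafs = NULL, seed = 1L,
                                config = NULL) {
  cfg <- if (is.null(config)) phenotypeModelConfig("causal_model")
         else config
  streams <- c("ccgwas", "fammeta_two_grandparents",
               "fammeta_four_grandparents")
  res <- .runReplicates(cfg$model, "three_generation", cfg, testMafs,
                        streams, nReplicates, seed)
  .tabulate(res, alpha, nReplicates)
}

#' Simulate one complete study
#'
#' Convenience wrapper producing a cohort, genotypes for the configured
#' variants, and a dichotomized phenotype in one call.
#'
#' @param model phenotype model.
#' @param mode family topology.
#' @param seed integer seed.
#' @param config optional [phenotypeModelConfig()] override.
#' @param nTwoChild,nThreeChild family counts.
#' @return list with elements `cohort`, `genotypes`, `phenotypes`.
#' @export
simulateStudy <- function(model = "causal_model",
                          mode = c("nuclear", "three_generation"),
                          seed = 1L, config = NULL,
                          nTwoChild = 200, nThreeChild = 200) {
  mode <- match.arg(mode)
  cfg <- if (is.null(config)) phenotypeModelConfig(model) else config
  seeds <- .spawnSeeds(seed, 4L)
  coh <- if (mode == "nuclear")
    generateCohort(nTwoChild, nThreeChild, seed = seeds[1L])
  else generateThreeGenerationCohort(nTwoChild, nThreeChild,
                                     seed = seeds[1L])
  fg <- drawFounderGenotypes(cfg$mafs, founderIds(coh), seed = seeds[2L])
  gt <- geneDrop(coh, fg, seed = seeds[3L])
  ph <- simulatePhenotype(coh, gt, cfg, seed = seeds[4L])
  ph <- dichotomize(ph, cfg$prevalence)
  list(cohort = coh, genotypes = gt, phenotypes = ph)
}
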