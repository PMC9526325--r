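# LT-FH: posterior mean genetic liability conditional on an individual's
# own case-control status and the statuses of parents and siblings, under
# the liability-threshold model, followed by a linear association test of
# the scores on genotype.

#' Liability threshold for a given prevalence
#'
#' The standard-normal upper-`prevalence` quantile: an individual is a case
#' when their liability exceeds this threshold.
#'
#' @param prevalence case fraction in (0, 1).
#' @return numeric threshold.
#' @examples
#' liabilityThreshold(0.5)   # 0
#' liabilityThreshold(0.3)   # 0.5244
#' @export
liabilityThreshold <- function(prevalence) {
  if (any(!is.finite(prevalence)) || any(prevalence <= 0 | prevalence >= 1))
    stop("prevalence must lie strictly in (0, 1)", call. = FALSE)
  qnorm(1 - prevalence)
}

.configKey <- function(own, npObs, npAff, nSib, nAffSib) {
  paste(own, npObs, npAff, nSib, nAffSib, sep = ":")
}

# Joint covariance of (eps_oe, eps_og, eps_p1, eps_p2, eps_s1..eps_sk):
# environmental component independent of everything; genetic component has
# variance h2 and covariance 0.5*h2 with each first-degree relative;
# relatives have unit total-liability variance, parents are unrelated to
# each other, siblings have pairwise covariance 0.5*h2 with each other and
# with each parent.
.ltfhSigma <- function(h2, maxSiblings) {
  d <- 4L + maxSiblings
  S <- matrix(0.5 * h2, d, d)
  S[1L, ] <- S[, 1L] <- 0
  S[3L, 4L] <- S[4L, 3L] <- 0
  diag(S) <- c(1 - h2, h2, rep(1, 2L + maxSiblings))
  S
}

#' Build the posterior mean genetic liability table
#'
#' Draws `nmc` joint Monte-Carlo samples of the environmental and genetic
#' liability components of an index individual together with the
#' liabilities of two parents and up to `maxSiblings` siblings from the
#' multivariate normal liability model, converts liabilities to
#' case-control statuses at the threshold implied by `prevalence`, and
#' averages the genetic component over the samples matching each
#' family-history configuration (own status; 0, 1 or 2 observed parents
#' with their affected count; 0..`maxSiblings` observed siblings with their
#' affected count). Unobserved parent statuses are marginalized simply by
#' not conditioning on them.
#'
#' @param h2 liability-scale heritability in (0, 1).
#' @param prevalence population case fraction in (0, 1).
#' @param nmc number of Monte-Carlo draws (>= 1e5).
#' @param maxSiblings largest sibling count tabulated.
#' @param seed integer seed for the draws.
#' @return a [PosteriorLiabilityTable-class].
#' @examples
#' \donttest{
#' tab <- buildPosteriorTable(h2 = 0.28, prevalence = 0.3, nmc = 2e5)
#' posteriorLiability(tab, ownStatus = 1, nAffectedParents = 0,
#'                    nSiblings = 0, nAffectedSiblings = 0,
#'                    nParentsObserved = 0)  # ~ 0.3245
#' }
#' @export
buildPosteriorTable <- function(h2 = 0.28, prevalence = 0.3, nmc = 1e6,
                                maxSiblings = 2L, seed = 1L) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie in (0, 1)", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  if (nmc < 1e5) stop("nmc must be at least 1e5", call. = FALSE)
  maxSiblings <- as.integer(maxSiblings)
  set.seed(as.integer(seed))

  t <- liabilityThreshold(prevalence)
  S <- .ltfhSigma(h2, maxSiblings)
  d <- ncol(S)
  E <- matrix(rnorm(nmc * d), nmc, d) %*% chol(S)

  og <- E[, 2L]
  So <- (E[, 1L] + og) > t
  Sp1 <- E[, 3L] > t
  Sp2 <- E[, 4L] > t
  psum <- Sp1 + Sp2
  sibCum <- matrix(0L, nmc, maxSiblings + 1L)   # col k+1: affected among first k sibs
  if (maxSiblings > 0L)
    for (k in seq_len(maxSiblings))
      sibCum[, k + 1L] <- sibCum[, k] + ((E[, 4L + k] > t))

  rows <- list()
  for (own in 0:1) {
    mOwn <- So == own
    for (npObs in 0:2) for (npAff in 0:npObs) {
      mPar <- switch(npObs + 1L, TRUE, Sp1 == npAff, psum == npAff)
      for (nSib in 0:maxSiblings) for (naff in 0:nSib) {
        mSib <- if (nSib == 0L) TRUE else sibCum[, nSib + 1L] == naff
        sel <- mOwn & mPar & mSib
        nm <- sum(sel)
        if (nm > 0L) {
          v <- og[sel]
          sc <- mean(v)
          se <- stats::sd(v) / sqrt(nm)
        } else {
          sc <- NA_real_; se <- NA_real_
          warning(sprintf(
            "no Monte-Carlo samples match configuration %s; increase nmc",
            .configKey(own, npObs, npAff, nSib, naff)), call. = FALSE)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          own_status = own, n_parents_observed = npObs,
          n_affected_parents = npAff, n_siblings = nSib,
          n_affected_siblings = naff, score = sc, se = se,
          n_match = nm, prob = nm / nmc)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("PosteriorLiabilityTable", table = tab, h2 = h2,
      prevalence = prevalence, nmc = nmc, seed = as.numeric(seed),
      threshold = t)
}

#' Look up posterior mean genetic liabilities
#'
#' Pure table lookup: identical configurations always yield identical
#' scores. All arguments are vectorized and recycled to a common length.
#'
#' @param table a [PosteriorLiabilityTable-class].
#' @param ownStatus 0/1 own case-control status.
#' @param nAffectedParents affected among the observed parents.
#' @param nSiblings number of observed siblings.
#' @param nAffectedSiblings affected among the observed siblings.
#' @param nParentsObserved number of parents with known status (0, 1 or 2).
#' @return numeric vector of posterior mean genetic liabilities.
#' @export
posteriorLiability <- function(table, ownStatus, nAffectedParents = 0,
                               nSiblings = 0, nAffectedSiblings = 0,
                               nParentsObserved = 2) {
  tab <- liabilityTable(table)
  key <- .configKey(ownStatus, nParentsObserved, nAffectedParents,
                    nSiblings, nAffectedSiblings)
  idx <- match(key, .configKey(tab$own_status, tab$n_parents_observed,
                               tab$n_affected_parents, tab$n_siblings,
                               tab$n_affected_siblings))
  if (anyNA(idx))
    stop("configuration(s) outside the table: ",
         paste(unique(key[is.na(idx)]), collapse = ", "), call. = FALSE)
  sc <- tab$score[idx]
  if (anyNA(sc))
    stop("requested configuration(s) had no Monte-Carlo support: ",
         paste(unique(key[is.na(sc)]), collapse = ", "), call. = FALSE)
  sc
}

#' Per-offspring LT-FH liability scores
#'
#' Maps each offspring of a dichotomized cohort to its posterior mean
#' genetic liability, using the offspring's own status and both parents'
#' statuses; with `useSiblings = TRUE` the statuses of the co-simulated
#' siblings (the family's other offspring) enter the configuration as
#' well.
#'
#' @param cohort a [FamCohort-class] in nuclear mode.
#' @param phenos a dichotomized [PhenotypeSet-class] covering the cohort.
#' @param table a [PosteriorLiabilityTable-class].
#' @param useSiblings include sibling statuses in the configuration
#'   (default `FALSE`: parents only, the configuration used in the power
#'   and type-I studies).
#' @return data.frame with columns `individual_id` and `score`, one row per
#'   offspring in member order.
#' @export
ltfhScores <- function(cohort, phenos, table, useSiblings = FALSE) {
  m <- members(cohort)
  ph <- .phenoData(phenos)
  z <- ph$Z[match(m$individual_id, ph$individual_id)]
  if (anyNA(z)) stop("phenotypes must be dichotomized first", call. = FALSE)
  off <- which(m$role == "offspring")
  own <- z[off]
  zF <- z[match(m$father_id[off], m$individual_id)]
  zM <- z[match(m$mother_id[off], m$individual_id)]
  famAff <- tapply(own, m$family_id[off], sum)
  famN <- tapply(own, m$family_id[off], length)
  fidx <- match(as.character(m$family_id[off]), names(famAff))
  nSib <- as.integer(famN[fidx]) - 1L
  nAffSib <- as.integer(famAff[fidx]) - own
  if (!useSiblings) { nSib <- nSib * 0L; nAffSib <- nAffSib * 0L }
  sc <- posteriorLiability(table, own, nAffectedParents = zF + zM,
                           nSiblings = nSib, nAffectedSiblings = nAffSib,
                           nParentsObserved = 2)
  data.frame(individual_id = m$individual_id[off], score = sc)
}

#' LT-FH association test
#'
#' Regression of the offspring posterior mean genetic liabilities
#' ([ltfhScores()]) on offspring genotype, adjusting for age and sex by
#' default. Because siblings' scores are built from shared family history
#' they are strongly correlated within sibships, so the default engine is
#' a linear mixed model with a sibship random intercept (fitted as
#' closed-form GLS with moment-estimated variance components); plain
#' ordinary least squares is available via `engine = "ols"` but is
#' anti-conservative under the null for family data.
#'
#' @inheritParams ccgwasTest
#' @param table a [PosteriorLiabilityTable-class].
#' @param useSiblings see [ltfhScores()].
#' @param engine `"gls"` (sibship random intercept, default) or `"ols"`.
#' @return an [AssociationResult-class].
#' @export
ltfhTest <- function(cohort, genoTable, phenos, table, variant,
                     adjustCovariates = TRUE, useSiblings = FALSE,
                     engine = c("gls", "ols")) {
  engine <- match.arg(engine)
  d <- .offspringDesign(cohort, genoTable, variant, adjustCovariates)
  sc <- ltfhScores(cohort, phenos, table, useSiblings = useSiblings)
  y <- sc$score[match(d$offspring$individual_id, sc$individual_id)]
  if (stats::var(y) == 0) {
    res <- .badFit(length(y))
    return(.asResult(res))
  }
  fit <- if (engine == "gls")
    .linearFitGLS(y, d$X, cluster = d$offspring$family_id)
  else .linearFit(y, d$X)
  .asResult(fit)
}
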