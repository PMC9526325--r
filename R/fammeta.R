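# Fam-meta: a relatives' logistic regression (relative status on the
# family's averaged proband genotype, adjusting for the averaged proband
# phenotype and the relative's age and sex) combined with the probands'
# case-control regression through kinship-weighted inverse-variance
# meta-analysis.

.RELATIVE_ROLES <- c("parents", "two_grandparents", "four_grandparents")

#' Build relative records for the relatives' regression
#'
#' One record per selected ungenotyped relative: the relative's status, age
#' and sex, the mean genotype and mean case-control status of that family's
#' probands (the offspring), and the proband-relative kinship coefficient
#' (0.25 for parents, 0.125 for grandparents). `"two_grandparents"` selects
#' one grandparent pair (paternal or maternal) uniformly at random per
#' family.
#'
#' @param cohort a [FamCohort-class]; must be in `"three_generation"` mode
#'   for the grandparent roles and `"nuclear"` mode for `"parents"`.
#' @param genoTable a [GenotypeTable-class].
#' @param phenos a dichotomized [PhenotypeSet-class].
#' @param variant variant id whose proband genotypes are averaged.
#' @param relativeRole `"parents"`, `"two_grandparents"` or
#'   `"four_grandparents"`.
#' @param seed optional seed for the random grandparent-pair selection.
#' @return data.frame with columns `relative_id`, `relative_status`,
#'   `relative_age`, `relative_sex`, `proband_genotype_mean`,
#'   `proband_phenotype_mean`, `phi`.
#' @export
buildRelativeRecords <- function(cohort, genoTable, phenos, variant,
                                 relativeRole = c("parents",
                                                  "two_grandparents",
                                                  "four_grandparents"),
                                 seed = NULL) {
  relativeRole <- match.arg(relativeRole)
  m <- members(cohort)
  mode <- cohortMode(cohort)
  if (relativeRole == "parents" && mode != "nuclear")
    stop("role 'parents' requires a nuclear cohort", call. = FALSE)
  if (relativeRole != "parents" && mode != "three_generation")
    stop("grandparent roles require a three-generation cohort",
         call. = FALSE)
  .maybeSeed(seed)

  ph <- .phenoData(phenos)
  z <- ph$Z[match(m$individual_id, ph$individual_id)]
  if (anyNA(z)) stop("phenotypes must be dichotomized first", call. = FALSE)
  G <- genotypes(genoTable)
  off <- m$role == "offspring"
  g <- G[as.character(m$individual_id[off]), variant]
  gMean <- tapply(g, m$family_id[off], mean)
  zMean <- tapply(z[off], m$family_id[off], mean)

  rel <- switch(relativeRole,
    parents = m[m$role %in% c("father", "mother"), , drop = FALSE],
    four_grandparents = m[m$generation == 0L &
                            m$role != "father" & m$role != "mother" &
                            startsWith(m$role, "grand"), , drop = FALSE],
    two_grandparents = {
      gp <- m[startsWith(m$role, "grand"), , drop = FALSE]
      fids <- unique(gp$family_id)
      side <- ifelse(runif(length(fids)) < 0.5, "paternal", "maternal")
      keep <- paste0(gp$family_id, ":", sub("^grand[a-z]+_", "", gp$role)) %in%
        paste0(fids, ":", side)
      gp[keep, , drop = FALSE]
    })
  phi <- if (relativeRole == "parents") 0.25 else 0.125
  fidx <- match(as.character(rel$family_id), names(gMean))
  data.frame(relative_id = rel$individual_id,
             relative_status = z[match(rel$individual_id, m$individual_id)],
             relative_age = rel$age, relative_sex = rel$sex,
             proband_genotype_mean = as.numeric(gMean[fidx]),
             proband_phenotype_mean = as.numeric(zMean[fidx]),
             phi = phi, stringsAsFactors = FALSE)
}

#' Relatives' logistic regression
#'
#' Logistic regression of the relatives' case-control status on the
#' averaged proband genotype, adjusting for the averaged proband phenotype
#' and the relative's age and sex. The reported effect is the coefficient
#' of the averaged proband genotype.
#'
#' @param records data.frame from [buildRelativeRecords()].
#' @return an [AssociationResult-class].
#' @export
relativeTest <- function(records) {
  X <- cbind(1, records$proband_genotype_mean,
             records$proband_phenotype_mean, records$relative_age,
             records$relative_sex)
  .asResult(.logisticFit(as.numeric(records$relative_status), X))
}

#' Kinship-weighted inverse-variance meta combination
#'
#' Combines the probands' and relatives' regression coefficients as
#' \deqn{T_{meta} = \frac{\hat\beta^P/\widehat{var}(\hat\beta^P) +
#'   2\phi\,\hat\beta^R/\widehat{var}(\hat\beta^R)}
#'   {\sqrt{1/\widehat{var}(\hat\beta^P) +
#'   4\phi^2/\widehat{var}(\hat\beta^R)}}}
#' with a two-sided normal p-value. The kinship weight `2 * phi` equals the
#' expected attenuation of the relatives' coefficient (0.5 for parents,
#' 0.25 for grandparents).
#'
#' @param probandResult,relativeResult [AssociationResult-class] objects
#'   (or plain lists with `beta`/`variance`/`converged`).
#' @param phi kinship coefficient between proband and relative.
#' @return a [MetaResult-class].
#' @export
combineMeta <- function(probandResult, relativeResult, phi) {
  bp <- probandResult@beta; vp <- probandResult@variance
  br <- relativeResult@beta; vr <- relativeResult@variance
  conv <- isTRUE(probandResult@converged) &&
    isTRUE(relativeResult@converged)
  if (conv && (!is.finite(vp) || vp <= 0 || !is.finite(vr) || vr <= 0))
    stop("variances must be positive", call. = FALSE)
  if (conv) {
    t <- (bp / vp + 2 * phi * br / vr) / sqrt(1 / vp + 4 * phi^2 / vr)
    p <- 2 * pnorm(-abs(t))
  } else {
    t <- NA_real_; p <- NA_real_
  }
  new("MetaResult", tMeta = t, pvalue = p, proband = probandResult,
      relative = relativeResult, phi = phi, converged = conv)
}

#' Fam-meta association test
#'
#' Runs the probands' case-control regression ([ccgwasTest()], offspring
#' only) and the relatives' regression ([relativeTest()]) for one variant
#' and combines them with [combineMeta()] using the kinship coefficient of
#' the chosen relative role.
#'
#' @inheritParams ccgwasTest
#' @inheritParams buildRelativeRecords
#' @return a [MetaResult-class]; flagged non-converged if either component
#'   regression failed.
#' @export
fammetaTest <- function(cohort, genoTable, phenos, variant,
                        relativeRole = "parents", adjustCovariates = TRUE,
                        seed = NULL) {
  pr <- ccgwasTest(cohort, genoTable, phenos, variant,
                   adjustCovariates = adjustCovariates)
  rec <- buildRelativeRecords(cohort, genoTable, phenos, variant,
                              relativeRole = relativeRole, seed = seed)
  rr <- relativeTest(rec)
  combineMeta(pr, rr, phi = rec$phi[1L])
}
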