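#' @import methods
#' @importFrom stats rnorm runif rbinom qnorm pnorm pt dnorm quantile
#'   median qchisq qbeta plogis setNames complete.cases
#' @importFrom utils read.table write.table
NULL

.ROLES <- c("father", "mother", "offspring",
            "grandfather_paternal", "grandmother_paternal",
            "grandfather_maternal", "grandmother_maternal")

.MALE_ROLES   <- c("father", "grandfather_paternal", "grandfather_maternal")
.FEMALE_ROLES <- c("mother", "grandmother_paternal", "grandmother_maternal")

#' FamCohort: a simulated cohort of families
#'
#' Container for the pedigree layer of a simulated cohort: one row per
#' individual with family membership, role, sex, age in years, generation
#' label (0 = oldest) and parent links. Two family topologies are supported:
#' nuclear families (two parents, two or three offspring) and
#' three-generation families that add all four grandparents.
#'
#' @slot members data.frame with columns `individual_id`, `family_id`,
#'   `father_id`, `mother_id` (`NA` for founders), `role`, `sex`
#'   (0 = male, 1 = female), `age` (years), `generation`.
#' @slot mode either `"nuclear"` or `"three_generation"`.
#'
#' @seealso [generateCohort()], [generateThreeGenerationCohort()]
#' @export
setClass("FamCohort",
         representation(members = "data.frame", mode = "character"))

setValidity("FamCohort", function(object) {
  m <- object@members
  need <- c("individual_id", "family_id", "father_id", "mother_id",
            "role", "sex", "age", "generation")
  if (!all(need %in% names(m)))
    return(paste("members must have columns:", paste(need, collapse = ", ")))
  if (!object@mode %in% c("nuclear", "three_generation"))
    return("mode must be 'nuclear' or 'three_generation'")
  if (nrow(m) == 0L) return(TRUE)
  if (anyDuplicated(m$individual_id)) return("duplicate individual ids")
  if (!all(m$role %in% .ROLES)) return("unknown role")
  if (any(m$sex[m$role %in% .MALE_ROLES] != 0L) ||
      any(m$sex[m$role %in% .FEMALE_ROLES] != 1L))
    return("sex inconsistent with parental/grandparental role")
  if (anyNA(m$age)) return(TRUE)   # imported pedigrees may lack ages
  off <- m$role == "offspring"
  if (any(m$age[off] < 18 | m$age[off] > 45))
    return("offspring age outside [18, 45]")
  # mother/father age rules, scanned per family
  byfam <- split(m, m$family_id)
  for (f in byfam) {
    kid <- max(f$age[f$role == "offspring"])
    mo  <- f$age[f$role == "mother"]
    fa  <- f$age[f$role == "father"]
    gap <- mo - kid
    if (gap < 20 - 1e-9 || gap > 45 + 1e-9)
      return("mother - oldest child age gap outside [20, 45]")
    if (abs(fa - mo) > 5 + 1e-9) return("father/mother age gap exceeds 5")
    if (fa - kid < 20 - 1e-9) return("father less than 20 years older than oldest child")
  }
  TRUE
})

#' GenotypeTable: additive genotype codes for a cohort
#'
#' Integer matrix of minor-allele counts (0/1/2), individuals in rows
#' (rownames are individual ids) and variants in columns, with a per-variant
#' annotation table carrying the minor-allele frequency used to simulate
#' founders.
#'
#' @slot geno integer matrix, entries in \{0, 1, 2\}.
#' @slot variants data.frame with columns `variant_id`, `maf`.
#' @export
setClass("GenotypeTable",
         representation(geno = "matrix", variants = "data.frame"))

setValidity("GenotypeTable", function(object) {
  g <- object@geno
  if (length(g) && !all(g %in% 0:2)) return("genotype codes must be 0, 1 or 2")
  if (ncol(g) != nrow(object@variants))
    return("variants table must have one row per genotype column")
  if (!all(c("variant_id", "maf") %in% names(object@variants)))
    return("variants must have columns variant_id, maf")
  TRUE
})

#' PhenotypeSet: liability-scale phenotypes and case-control status
#'
#' Per-individual continuous liability `Y`, binary status `Z` (`NA` until
#' dichotomized) and the stored additive decomposition of `Y` into its
#' simulated components, so that `Y` always reconstructs as their sum.
#'
#' @slot data data.frame with columns `individual_id`, `family_id`, `age`,
#'   `sex`, `Y`, `Z`, and component columns `snp_term`, `interaction_term`,
#'   `age_term`, `sex_term`, `polygenic`, `error`.
#' @slot model one of `"null_model"`, `"causal_model"`, `"interaction_model"`.
#' @slot threshold the empirical liability threshold used to fill `Z`
#'   (`NA` until [dichotomize()] is applied).
#' @export
setClass("PhenotypeSet",
         representation(data = "data.frame", model = "character",
                        threshold = "numeric"))

.PHENO_COMPONENTS <- c("snp_term", "interaction_term", "age_term",
                       "sex_term", "polygenic", "error")

setValidity("PhenotypeSet", function(object) {
  d <- object@data
  need <- c("individual_id", "family_id", "age", "sex", "Y", "Z",
            .PHENO_COMPONENTS)
  if (!all(need %in% names(d)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  if (nrow(d)) {
    recon <- rowSums(as.matrix(d[, .PHENO_COMPONENTS]))
    if (max(abs(recon - d$Y)) > 1e-8)
      return("Y does not equal the sum of its stored components")
    z <- d$Z[!is.na(d$Z)]
    if (length(z) && !all(z %in% 0:1)) return("Z must be 0/1 or NA")
  }
  TRUE
})

#' PosteriorLiabilityTable: posterior mean genetic liabilities
#'
#' Lookup table mapping each family-history configuration (own case-control
#' status, number of observed parents and how many are affected, number of
#' observed siblings and how many are affected) to the Monte-Carlo estimate
#' of the posterior mean genetic liability under the liability-threshold
#' model, together with the configuration probability and Monte-Carlo
#' standard error.
#'
#' @slot table data.frame with columns `own_status`, `n_parents_observed`,
#'   `n_affected_parents`, `n_siblings`, `n_affected_siblings`, `score`,
#'   `se`, `n_match`, `prob`.
#' @slot h2 liability-scale heritability.
#' @slot prevalence population case fraction.
#' @slot nmc number of Monte-Carlo draws used.
#' @slot seed RNG seed used for the draws.
#' @slot threshold liability threshold, `qnorm(1 - prevalence)`.
#' @export
setClass("PosteriorLiabilityTable",
         representation(table = "data.frame", h2 = "numeric",
                        prevalence = "numeric", nmc = "numeric",
                        seed = "numeric", threshold = "numeric"))

setValidity("PosteriorLiabilityTable", function(object) {
  t <- object@table
  need <- c("own_status", "n_parents_observed", "n_affected_parents",
            "n_siblings", "n_affected_siblings", "score", "se",
            "n_match", "prob")
  if (!all(need %in% names(t)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (object@h2 <= 0 || object@h2 >= 1) return("h2 must be in (0, 1)")
  if (object@prevalence <= 0 || object@prevalence >= 1)
    return("prevalence must be in (0, 1)")
  TRUE
})

#' AssociationResult: a single-variant association test result
#'
#' @slot beta effect estimate for the predictor of interest.
#' @slot variance sampling variance of `beta`.
#' @slot statistic Wald z statistic, `beta / sqrt(variance)`.
#' @slot pvalue two-sided normal p-value.
#' @slot n sample size used in the fit.
#' @slot converged whether the fit converged (rank-deficient designs and
#'   detected separation set this to `FALSE`).
#' @export
setClass("AssociationResult",
         representation(beta = "numeric", variance = "numeric",
                        statistic = "numeric", pvalue = "numeric",
                        n = "numeric", converged = "logical"))

setValidity("AssociationResult", function(object) {
  if (isTRUE(object@converged)) {
    if (!is.na(object@variance) && object@variance <= 0)
      return("variance must be positive for a converged fit")
    if (!is.na(object@pvalue) && (object@pvalue <= 0 || object@pvalue > 1))
      return("pvalue must lie in (0, 1]")
  }
  TRUE
})

#' MetaResult: kinship-weighted meta-analysis of proband and relative tests
#'
#' @slot tMeta combined statistic.
#' @slot pvalue two-sided normal p-value of `tMeta`.
#' @slot proband [AssociationResult-class] from the probands' regression.
#' @slot relative [AssociationResult-class] from the relatives' regression.
#' @slot phi kinship coefficient between proband and relative.
#' @slot converged `TRUE` only if both component regressions converged.
#' @export
setClass("MetaResult",
         representation(tMeta = "numeric", pvalue = "numeric",
                        proband = "AssociationResult",
                        relative = "AssociationResult",
                        phi = "numeric", converged = "logical"))
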