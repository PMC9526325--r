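#' Accessors for cohort, genotype and phenotype containers
#'
#' `members()` returns the pedigree data.frame; `cohortMode()` the family
#' topology; `nFamilies()`/`nIndividuals()` the counts; `offspringIds()` the
#' ids of the genotyped probands (the offspring generation);
#' `genotypes()`/`variantInfo()` the genotype matrix and variant annotation;
#' `phenotypes()` the phenotype data.frame; `liabilityTable()` the lookup
#' data.frame of a [PosteriorLiabilityTable-class].
#'
#' @param x the object.
#' @return the slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("cohortMode", function(x) standardGeneric("cohortMode"))
#' @rdname accessors
#' @export
setGeneric("nFamilies", function(x) standardGeneric("nFamilies"))
#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' @rdname accessors
#' @export
setGeneric("offspringIds", function(x) standardGeneric("offspringIds"))
#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))
#' @rdname accessors
#' @export
setGeneric("liabilityTable", function(x) standardGeneric("liabilityTable"))

#' @rdname accessors
setMethod("members", "FamCohort", function(x) x@members)
#' @rdname accessors
setMethod("cohortMode", "FamCohort", function(x) x@mode)
#' @rdname accessors
setMethod("nFamilies", "FamCohort",
          function(x) length(unique(x@members$family_id)))
#' @rdname accessors
setMethod("nIndividuals", "FamCohort", function(x) nrow(x@members))
#' @rdname accessors
setMethod("offspringIds", "FamCohort",
          function(x) x@members$individual_id[x@members$role == "offspring"])
#' @rdname accessors
setMethod("genotypes", "GenotypeTable", function(x) x@geno)
#' @rdname accessors
setMethod("variantInfo", "GenotypeTable", function(x) x@variants)
#' @rdname accessors
setMethod("phenotypes", "PhenotypeSet", function(x) x@data)
#' @rdname accessors
setMethod("liabilityTable", "PosteriorLiabilityTable", function(x) x@table)

setMethod("show", "FamCohort", function(object) {
  m <- object@members
  cat(sprintf("FamCohort (%s): %d individuals in %d families\n",
              object@mode, nrow(m), length(unique(m$family_id))))
  if (nrow(m)) {
    tab <- table(m$role)
    cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
})

setMethod("show", "GenotypeTable", function(object) {
  cat(sprintf("GenotypeTable: %d individuals x %d variants\n",
              nrow(object@geno), ncol(object@geno)))
  if (nrow(object@variants))
    cat("  MAFs:", paste(format(object@variants$maf), collapse = ", "), "\n")
})

setMethod("show", "PhenotypeSet", function(object) {
  d <- object@data
  cat(sprintf("PhenotypeSet (%s): %d individuals\n", object@model, nrow(d)))
  if (nrow(d)) {
    if (all(is.na(d$Z))) cat("  continuous liability only (not dichotomized)\n")
    else cat(sprintf("  cases: %d (%.3f), threshold %.4f\n",
                     sum(d$Z, na.rm = TRUE), mean(d$Z, na.rm = TRUE),
                     object@threshold))
  }
})

setMethod("show", "PosteriorLiabilityTable", function(object) {
  cat(sprintf(
    "PosteriorLiabilityTable: h2 = %.3f, prevalence = %.3f, threshold = %.4f\n",
    object@h2, object@prevalence, object@threshold))
  cat(sprintf("  %d configurations, %g Monte-Carlo draws (seed %d)\n",
              nrow(object@table), object@nmc, as.integer(object@seed)))
})

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf(
    "AssociationResult: beta = %.4g (se %.4g), z = %.3f, p = %.3g, n = %d%s\n",
    object@beta, sqrt(object@variance), object@statistic, object@pvalue,
    as.integer(object@n), if (object@converged) "" else " [NOT CONVERGED]"))
})

setMethod("show", "MetaResult", function(object) {
  cat(sprintf("MetaResult (phi = %.3f): T_meta = %.3f, p = %.3g%s\n",
              object@phi, object@tMeta, object@pvalue,
              if (object@converged) "" else " [NOT CONVERGED]"))
  cat("  proband:  "); show(object@proband)
  cat("  relative: "); show(object@relative)
})
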