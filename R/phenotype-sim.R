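# Liability-scale phenotype simulation: per-SNP effects sized by variance
# explained, family-correlated polygenic component, age/sex covariate
# effects, optional age-by-genotype interaction, and threshold
# dichotomization at a fixed prevalence.

.MODELS <- c("null_model", "causal_model", "interaction_model")

# Residual variance for the interaction model: carried over from the
# causal model (the age-by-genotype interaction is added on top, so total
# phenotypic variance is ~1.2 rather than 1; the empirical threshold rule
# keeps the prevalence at 0.3 regardless). A variance-normalizing
# alternative, calibrated so Var(Y) = 1 from 10^6 simulated individuals
# (seed 20260101), is 0.3657 and can be supplied via the sigmaE2 argument.
.MODEL3_SIGMA_E2 <- 0.57

#' Default liability-model configuration
#'
#' Bundles the simulation parameters of the three phenotype models:
#' `null_model` (no SNP effects), `causal_model` (eight causal variants,
#' each explaining `pvePerSnp` of the phenotypic variance) and
#' `interaction_model` (adds an age-by-genotype interaction). Defaults:
#' MAFs 0.01-0.50, per-SNP variance explained 0.01 (causal) or 0.005
#' (interaction), polygenic variance 0.2, age coefficient 0.015/year, sex
#' coefficient 0.45 (female = 1), interaction coefficient 0.02, prevalence
#' 0.3, and residual variance 0.65 (null) or 0.57 (causal and
#' interaction; the interaction term is added on top of the causal-model
#' variance budget).
#'
#' @param model one of `"null_model"`, `"causal_model"`,
#'   `"interaction_model"`.
#' @param mafs minor-allele frequencies of the causal variants.
#' @param pvePerSnp phenotypic variance explained per causal variant.
#' @param sigmaG2 polygenic variance on the liability scale.
#' @param sigmaE2 residual variance; defaults depend on `model`.
#' @param ageCoef,sexCoef,interactionAgeCoef fixed-effect coefficients.
#' @param prevalence population case fraction used by [dichotomize()].
#' @return a named list of class `phenotypeModelConfig`.
#' @export
phenotypeModelConfig <- function(model = c("null_model", "causal_model",
                                           "interaction_model"),
                                 mafs = c(0.01, 0.02, 0.05, 0.10,
                                          0.20, 0.30, 0.40, 0.50),
                                 pvePerSnp = NULL, sigmaG2 = 0.2,
                                 sigmaE2 = NULL, ageCoef = 0.015,
                                 sexCoef = 0.45, interactionAgeCoef = 0.02,
                                 prevalence = 0.3) {
  model <- match.arg(model)
  if (is.null(pvePerSnp))
    pvePerSnp <- switch(model, null_model = 0, causal_model = 0.01,
                        interaction_model = 0.005)
  if (is.null(sigmaE2))
    sigmaE2 <- switch(model, null_model = 0.65, causal_model = 0.57,
                      interaction_model = .MODEL3_SIGMA_E2)
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly in (0, 1)", call. = FALSE)
  structure(list(model = model, mafs = mafs, pvePerSnp = pvePerSnp,
                 sigmaG2 = sigmaG2, sigmaE2 = sigmaE2, ageCoef = ageCoef,
                 sexCoef = sexCoef,
                 interactionAgeCoef = interactionAgeCoef,
                 prevalence = prevalence),
            class = "phenotypeModelConfig")
}

#' Per-variant effect size from variance explained
#'
#' Returns `sqrt(pve / (2 * maf * (1 - maf)))`, the additive effect such
#' that a variant in Hardy-Weinberg equilibrium with the given MAF explains
#' the fraction `pve` of phenotypic variance.
#'
#' @param maf minor-allele frequency in (0, 0.5\].
#' @param pve phenotypic variance explained, > 0.
#' @return numeric effect size (vectorized over `maf`).
#' @examples
#' effectSize(0.5, 0.01)   # 0.1414214
#' effectSize(0.01, 0.01)  # 0.7106691
#' @export
effectSize <- function(maf, pve) {
  if (any(!is.finite(maf)) || any(maf <= 0 | maf > 0.5))
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  if (any(!is.finite(pve)) || any(pve <= 0))
    stop("pve must be positive", call. = FALSE)
  sqrt(pve / (2 * maf * (1 - maf)))
}

#' Simulate the family-correlated polygenic component
#'
#' Draws, independently for each family, a zero-mean multivariate normal
#' vector with covariance `2 * phi * sigmaG2`, where `phi` is the family's
#' kinship matrix; the factor 2 (numerator relationship scaling) makes each
#' individual's polygenic variance equal `sigmaG2` and the parent-offspring
#' covariance `0.5 * sigmaG2`.
#'
#' @param cohort a [FamCohort-class].
#' @param sigmaG2 polygenic variance (>= 0).
#' @param seed optional integer seed.
#' @return numeric vector of polygenic values in `members(cohort)` row
#'   order, named by individual id.
#' @export
simulatePolygenic <- function(cohort, sigmaG2 = 0.2, seed = NULL) {
  m <- members(cohort)
  if (sigmaG2 < 0) stop("sigmaG2 must be non-negative", call. = FALSE)
  .maybeSeed(seed)
  out <- numeric(nrow(m))
  names(out) <- as.character(m$individual_id)
  if (!nrow(m) || sigmaG2 == 0) return(out)

  famSize <- table(m$family_id)
  # families of equal size share a topology, hence a Cholesky factor
  for (sz in unique(as.integer(famSize))) {
    fids <- sort(as.integer(names(famSize)[famSize == sz]))
    rows <- which(m$family_id %in% fids)
    phi <- .kinshipFromPed(m[m$family_id == fids[1L], , drop = FALSE])
    L <- chol(2 * phi * sigmaG2)    # upper triangular, cov = t(L) %*% L
    nf <- length(fids)
    z <- matrix(rnorm(sz * nf), sz, nf)
    # member rows are id-ordered, so families form contiguous, ascending
    # blocks whose within-family order matches the kinship row order
    out[rows] <- as.vector(crossprod(L, z))
  }
  out
}

#' Simulate continuous liabilities
#'
#' Computes the liability `Y` of every cohort member from the selected
#' model formula and stores each additive component:
#' * `null_model`: `Y = ageCoef*age + sexCoef*sex + polygenic + error`
#' * `causal_model`: adds `sum_k beta_k g_k` over the causal variants, with
#'   `beta_k` from [effectSize()]
#' * `interaction_model`: additionally adds
#'   `interactionAgeCoef * age * sum_k beta_k g_k`
#'
#' The error is Normal(0, `sigmaE2`); age is in years, uncentered; sex is
#' coded female = 1, male = 0.
#'
#' @param cohort a [FamCohort-class].
#' @param genoTable a [GenotypeTable-class] covering all members (ignored
#'   under `null_model`, may be `NULL` then).
#' @param config a [phenotypeModelConfig()] list.
#' @param seed optional integer seed.
#' @return a [PhenotypeSet-class] with continuous `Y` (status `Z` is `NA`
#'   until [dichotomize()]).
#' @export
simulatePhenotype <- function(cohort, genoTable = NULL,
                              config = phenotypeModelConfig(), seed = NULL) {
  m <- members(cohort)
  n <- nrow(m)
  .maybeSeed(seed)

  snp <- numeric(n)
  inter <- numeric(n)
  if (config$model != "null_model") {
    if (is.null(genoTable)) stop("genotypes required for this model",
                                 call. = FALSE)
    G <- genotypes(genoTable)
    ids <- as.character(m$individual_id)
    if (!all(ids %in% rownames(G)))
      stop("genotypes missing for some cohort members", call. = FALSE)
    vi <- variantInfo(genoTable)
    betas <- effectSize(vi$maf, config$pvePerSnp)
    snp <- as.vector(G[ids, , drop = FALSE] %*% betas)
    if (config$model == "interaction_model")
      inter <- config$interactionAgeCoef * m$age * snp
  }
  gamma <- simulatePolygenic(cohort, config$sigmaG2)
  err <- rnorm(n, 0, sqrt(config$sigmaE2))
  ageT <- config$ageCoef * m$age
  sexT <- config$sexCoef * m$sex
  d <- data.frame(individual_id = m$individual_id,
                  family_id = m$family_id, age = m$age, sex = m$sex,
                  Y = snp + inter + ageT + sexT + as.numeric(gamma) + err,
                  Z = NA_integer_,
                  snp_term = snp, interaction_term = inter,
                  age_term = ageT, sex_term = sexT,
                  polygenic = as.numeric(gamma), error = err,
                  stringsAsFactors = FALSE)
  new("PhenotypeSet", data = d, model = config$model,
      threshold = NA_real_)
}

#' Dichotomize liabilities at a target prevalence
#'
#' Case-control status is assigned by the empirical threshold rule: the
#' `round(n * prevalence)` individuals with the largest liabilities are
#' cases, so the realized case fraction equals the prevalence up to integer
#' rounding in every replicate. Ties in `Y` are broken deterministically by
#' individual id (smaller id ranks higher).
#'
#' @param phenos a [PhenotypeSet-class] with continuous `Y`.
#' @param prevalence target case fraction in (0, 1).
#' @return the [PhenotypeSet-class] with `Z` filled and the threshold (the
#'   largest control liability) recorded.
#' @export
dichotomize <- function(phenos, prevalence = 0.3) {
  if (length(prevalence) != 1L || !is.finite(prevalence) ||
      prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly in (0, 1)", call. = FALSE)
  d <- phenotypes(phenos)
  n <- nrow(d)
  k <- as.integer(round(n * prevalence))
  z <- integer(n)
  ord <- order(-d$Y, d$individual_id)
  z[ord[seq_len(k)]] <- 1L
  d$Z <- z
  thr <- if (k < n) d$Y[ord[k + 1L]] else -Inf
  initialize(phenos, data = d, threshold = thr)
}
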