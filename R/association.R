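# Regression engines shared by all three association tests, plus the
# case-control logistic-regression baseline on genotyped offspring.
# Internal fitters return plain lists for speed inside replicate loops; the
# exported wrappers return AssociationResult objects.

.asResult <- function(fit) {
  new("AssociationResult", beta = fit$beta, variance = fit$variance,
      statistic = fit$statistic, pvalue = fit$pvalue, n = fit$n,
      converged = fit$converged)
}

.badFit <- function(n) {
  list(beta = NA_real_, variance = NA_real_, statistic = NA_real_,
       pvalue = NA_real_, n = n, converged = FALSE)
}

# Ordinary least squares via QR; Wald z with a two-sided normal p-value.
.linearFit <- function(y, X, focus = 2L) {
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("need more observations than predictors", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) return(.badFit(n))
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(qrX))
  v <- sigma2 * XtXinv[focus, focus]
  if (!is.finite(v)) return(.badFit(n))
  v <- max(v, 1e-280)                    # exact fits: keep p-value defined
  z <- beta[focus] / sqrt(v)
  list(beta = unname(beta[focus]), variance = unname(v),
       statistic = unname(z),
       pvalue = max(2 * pnorm(-abs(z)), 1e-300), n = n,
       converged = TRUE)
}

# Logistic regression by iteratively reweighted least squares.
# Convergence: |delta log-likelihood| < 1e-8, at most `maxit` iterations.
# Detected separation (fitted probabilities pinned at 0/1 with diverging
# coefficients) is flagged as non-converged.
.logisticFit <- function(y, X, focus = 2L, maxit = 50L, tol = 1e-8) {
  n <- length(y)
  p <- ncol(X)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1", call. = FALSE)
  if (all(y == y[1L]))
    stop("response has a single class; logistic fit undefined", call. = FALSE)
  beta <- numeric(p)
  beta[1L] <- log(mean(y) / (1 - mean(y)))   # start at intercept-only MLE
  eta <- as.vector(X %*% beta)
  mu <- plogis(eta)
  ll <- sum(y * eta - log1p(exp(eta)))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    fit <- .lm.fit(X * sw, z * sw)
    if (fit$rank < p) return(.badFit(n))
    beta <- fit$coefficients
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    llNew <- sum(y * eta - log1p(exp(pmin(eta, 30))) -
                   pmax(eta - 30, 0))       # stable log1p(exp())
    if (!is.finite(llNew)) return(.badFit(n))
    if (abs(llNew - ll) < tol) { converged <- TRUE; ll <- llNew; break }
    ll <- llNew
  }
  # separation heuristic: fitted probabilities pinned at 0/1, or
  # coefficients diverging without the deviance settling
  if (any(mu < 1e-8 | mu > 1 - 1e-8) || max(abs(beta)) > 1e3)
    return(.badFit(n))
  if (!converged) return(.badFit(n))
  w <- pmax(mu * (1 - mu), 1e-12)
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(cov)) return(.badFit(n))
  v <- cov[focus, focus]
  if (!is.finite(v) || v <= 0) return(.badFit(n))
  zstat <- beta[focus] / sqrt(v)
  list(beta = unname(beta[focus]), variance = unname(v),
       statistic = unname(zstat), pvalue = 2 * pnorm(-abs(zstat)), n = n,
       converged = TRUE)
}

# Exchangeable-cluster GLS solve: given a (possibly pre-whitened) response
# and design, estimate the within-cluster residual covariance by moments
# from a provisional OLS fit and solve the GLS normal equations through
# per-cluster column sums (Woodbury form, no per-cluster inversion).
# Returns NULL on rank problems, or a list with beta, cov, and the moment
# estimates.
.glsSolve <- function(y, X, cluster) {
  n <- length(y)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) return(NULL)
  r <- y - X %*% qr.coef(qrX, y)
  Sr <- rowsum(r, cluster)
  Sr2 <- rowsum(r^2, cluster)
  mf <- as.vector(rowsum(rep(1, n), cluster))
  st2 <- sum(r^2) / (n - p)
  den <- sum(mf * (mf - 1))
  su2 <- if (den == 0) 0 else sum(Sr^2 - Sr2) / den
  su2 <- min(max(su2, 0), 0.999 * st2)
  se2 <- st2 - su2
  if (su2 == 0) {
    XtXinv <- chol2inv(qr.R(qrX))
    beta <- qr.coef(qrX, y)
    return(list(beta = as.vector(beta), cov = XtXinv * se2,
                su2 = 0, se2 = se2))
  }
  rho <- su2 / se2
  cf <- rho / (1 + rho * mf)
  Sx <- rowsum(X, cluster)
  Sy <- rowsum(y, cluster)
  A <- (crossprod(X) - crossprod(Sx, Sx * cf)) / se2
  b <- (crossprod(X, y) - crossprod(Sx, Sy * cf)) / se2
  cov <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  list(beta = as.vector(cov %*% b), cov = cov, su2 = su2, se2 = se2)
}

# Family-clustered linear fit: GLS under a sibship random-intercept model
# y = X beta + u_cluster + e, with the two variance components estimated by
# moments from OLS residuals (within-cluster mean cross-product).
# Responses built from shared family history (the LT-FH scores) are
# strongly correlated within sibships; ignoring that correlation inflates
# the Wald test badly when the genotype is itself family-correlated.
.linearFitGLS <- function(y, X, cluster, focus = 2L) {
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("need more observations than predictors",
                   call. = FALSE)
  g <- .glsSolve(y, X, cluster)
  if (is.null(g)) return(.badFit(n))
  v <- g$cov[focus, focus]
  if (!is.finite(v) || v <= 0) return(.badFit(n))
  z <- g$beta[focus] / sqrt(v)
  # cluster-level degrees of freedom: the variance components are
  # estimated from ~#clusters independent units
  df <- length(unique(cluster)) - p
  pv <- if (df > 0) 2 * pt(-abs(z), df) else 2 * pnorm(-abs(z))
  list(beta = g$beta[focus], variance = v, statistic = z,
       pvalue = max(pv, 1e-300), n = n, converged = TRUE)
}

# Family-clustered logistic fit: IRLS in which each weighted least-squares
# step is replaced by the exchangeable-cluster GLS solve on the working
# response (generalized estimating equations with an exchangeable working
# correlation and model-based variance). With no residual clustering the
# moment estimate vanishes and the fit reduces to ordinary IRLS.
.logisticFitGEE <- function(y, X, cluster, focus = 2L, maxit = 50L,
                            tol = 1e-8) {
  n <- length(y)
  p <- ncol(X)
  if (all(y == y[1L]))
    stop("response has a single class; logistic fit undefined", call. = FALSE)
  beta <- numeric(p)
  beta[1L] <- log(mean(y) / (1 - mean(y)))
  eta <- as.vector(X %*% beta)
  mu <- plogis(eta)
  ll <- sum(y * eta - log1p(exp(eta)))
  converged <- FALSE
  g <- NULL
  for (it in seq_len(maxit)) {
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    g <- .glsSolve(z * sw, X * sw, cluster)
    if (is.null(g)) return(.badFit(n))
    beta <- g$beta
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    llNew <- sum(y * eta - log1p(exp(pmin(eta, 30))) - pmax(eta - 30, 0))
    if (!is.finite(llNew)) return(.badFit(n))
    if (abs(llNew - ll) < tol) { converged <- TRUE; ll <- llNew; break }
    ll <- llNew
  }
  if (!converged || any(mu < 1e-8 | mu > 1 - 1e-8) ||
      max(abs(beta)) > 1e3)
    return(.badFit(n))
  v <- g$cov[focus, focus]
  if (!is.finite(v) || v <= 0) return(.badFit(n))
  zstat <- beta[focus] / sqrt(v)
  df <- length(unique(cluster)) - p
  pv <- if (df > 0) 2 * pt(-abs(zstat), df) else 2 * pnorm(-abs(zstat))
  list(beta = beta[focus], variance = v, statistic = zstat,
       pvalue = max(pv, 1e-300), n = n, converged = TRUE)
}

#' Linear association fit
#'
#' Ordinary least-squares regression of `response` on the columns of
#' `predictors` (supply an intercept column explicitly, or use the default
#' wrapper which prepends one). The Wald statistic and two-sided normal
#' p-value are reported for the `focus` column. Rank-deficient designs
#' yield a non-converged result.
#'
#' @param response numeric vector.
#' @param predictors design matrix (without intercept; one is prepended).
#' @param focus which predictor column the effect estimate refers to
#'   (1 = the first column of `predictors`).
#' @return an [AssociationResult-class].
#' @export
linearFit <- function(response, predictors, focus = 1L) {
  X <- cbind(1, as.matrix(predictors))
  .asResult(.linearFit(as.numeric(response), X, focus = focus + 1L))
}

#' Logistic association fit
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares (convergence when the log-likelihood changes by less than 1e-8,
#' at most 50 iterations), reporting the Wald statistic and two-sided
#' normal p-value for the `focus` predictor. A single-class response is an
#' error; detected separation returns a non-converged result.
#'
#' @inheritParams linearFit
#' @param response binary 0/1 vector containing both classes.
#' @return an [AssociationResult-class].
#' @export
logisticFit <- function(response, predictors, focus = 1L) {
  X <- cbind(1, as.matrix(predictors))
  .asResult(.logisticFit(as.numeric(response), X, focus = focus + 1L))
}

# Offspring design matrix for the proband-side tests: intercept, genotype
# at one variant, then optional age and sex.
.offspringDesign <- function(cohort, genoTable, variant, adjustCovariates) {
  m <- members(cohort)
  off <- m[m$role == "offspring", , drop = FALSE]
  G <- genotypes(genoTable)
  g <- G[as.character(off$individual_id), variant]
  X <- if (adjustCovariates) cbind(1, g, off$age, off$sex) else cbind(1, g)
  list(offspring = off, X = X)
}

#' Case-control GWAS baseline test
#'
#' Logistic regression of offspring case-control status on offspring
#' genotype, adjusting for age and sex (the simulated confounders) by
#' default. Only the offspring are used, mirroring a study where parental
#' genotypes are unavailable; with the default 400 nuclear families this is
#' n = 1000. Because the offspring sample contains sibships (correlated
#' statuses and genotypes), the default fit accounts for familial
#' relatedness through an exchangeable-sibship working correlation
#' (generalized estimating equations); `clusterCorrection = FALSE` gives
#' the plain independence fit.
#'
#' @param cohort a [FamCohort-class].
#' @param genoTable a [GenotypeTable-class].
#' @param phenos a dichotomized [PhenotypeSet-class].
#' @param variant variant id (column of the genotype table) to test.
#' @param adjustCovariates adjust for age and sex (default `TRUE`).
#' @param clusterCorrection account for sibship clustering (default
#'   `TRUE`).
#' @return an [AssociationResult-class].
#' @export
ccgwasTest <- function(cohort, genoTable, phenos, variant,
                       adjustCovariates = TRUE, clusterCorrection = TRUE) {
  d <- .offspringDesign(cohort, genoTable, variant, adjustCovariates)
  ph <- .phenoData(phenos)
  z <- ph$Z[match(d$offspring$individual_id, ph$individual_id)]
  if (anyNA(z)) stop("phenotypes must be dichotomized first", call. = FALSE)
  fit <- if (clusterCorrection)
    .logisticFitGEE(as.numeric(z), d$X, cluster = d$offspring$family_id)
  else .logisticFit(as.numeric(z), d$X)
  .asResult(fit)
}
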