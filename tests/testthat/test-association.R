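# Regression engines: agreement with reference implementations, closed
# forms, degenerate designs, and the CC-GWAS baseline.

test_that("linear fit matches the closed-form normal equations", {
  # 5-point example solved by hand via solve(t(X) X) t(X) y
  x <- c(1, 2, 3, 4, 5)
  y <- c(1.1, 1.9, 3.2, 3.9, 5.1)
  X <- cbind(1, x)
  betaRef <- solve(crossprod(X), crossprod(X, y))
  fit <- linearFit(y, cbind(x), focus = 1)
  expect_equal(fit@beta, betaRef[2], tolerance = 1e-12)

  exact <- linearFit(2 * x, cbind(x), focus = 1)
  expect_equal(exact@beta, 2, tolerance = 1e-12)
  expect_lt(exact@pvalue, 1e-12)
})

test_that("linear and logistic fits agree with lm/glm on random data", {
  set.seed(40)
  for (r in 1:20) {
    n <- sample(40:120, 1)
    X <- cbind(rnorm(n), runif(n), rbinom(n, 2, 0.3))
    yc <- drop(X %*% c(0.5, -1, 0.3)) + rnorm(n)
    fit <- linearFit(yc, X, focus = 1)
    ref <- summary(lm(yc ~ X))$coefficients
    expect_equal(fit@beta, ref[2, 1], tolerance = 1e-9)
    expect_equal(sqrt(fit@variance), ref[2, 2], tolerance = 1e-9)

    yb <- rbinom(n, 1, plogis(drop(X %*% c(0.8, -0.5, 0.4)) - 0.2))
    if (length(unique(yb)) < 2) next
    lfit <- logisticFit(yb, X, focus = 1)
    gref <- glm.fit(cbind(1, X), yb, family = binomial(),
                    control = glm.control(epsilon = 1e-12))
    if (!lfit@converged) next
    se <- sqrt(diag(chol2inv(qr.R(gref$qr))))
    expect_equal(lfit@beta, gref$coefficients[2], tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(sqrt(lfit@variance), se[2], tolerance = 1e-6)
  }
})

test_that("intercept-only logistic fit recovers log odds of the prevalence", {
  y <- rep(c(1L, 0L), c(300, 700))
  fit <- logisticFit(y, matrix(numeric(0), 1000, 0), focus = 0)
  expect_equal(fit@beta, log(0.3 / 0.7), tolerance = 1e-8)
})

test_that("degenerate designs are flagged, not mis-reported", {
  set.seed(41)
  y <- rep(0:1, each = 25)
  # perfect separation
  fit <- logisticFit(y, cbind(y), focus = 1)
  expect_false(fit@converged)
  # single-class response is an error
  expect_error(logisticFit(rep(1, 50), cbind(rnorm(50))), "class")
  # rank-deficient design
  x <- rnorm(50)
  lfit <- linearFit(rnorm(50), cbind(x, 2 * x), focus = 2)
  expect_false(lfit@converged)
})

test_that("null-predictor p-values are uniform", {
  set.seed(42)
  p <- replicate(400, {
    y <- rnorm(300)
    linearFit(y, cbind(rbinom(300, 2, 0.3)), focus = 1)@pvalue
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  expect_lt(abs(mean(p) - 0.5), 3 * sqrt(1 / 12 / 400))
})

test_that("Wald p-values are invariant to affine covariate rescaling", {
  set.seed(43)
  n <- 500
  g <- rbinom(n, 2, 0.3); age <- runif(n, 18, 80); sex <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + 0.3 * g + 0.01 * age))
  p1 <- logisticFit(y, cbind(g, age, sex), focus = 1)@pvalue
  p2 <- logisticFit(y, cbind(g, age / 10 - 3, sex * 2 - 1),
                    focus = 1)@pvalue
  expect_equal(p1, p2, tolerance = 1e-6)
  q1 <- linearFit(age, cbind(g, y), focus = 1)@pvalue
  q2 <- linearFit(age, cbind(g, 5 * y - 2), focus = 1)@pvalue
  expect_equal(q1, q2, tolerance = 1e-9)
})

test_that("family-clustered GLS reduces to OLS without clustering and is
           calibrated under a random-intercept model", {
  set.seed(44)
  y <- rnorm(100); X <- cbind(1, rnorm(100))
  ols <- famhist:::.linearFit(y, X)
  gls <- famhist:::.linearFitGLS(y, X, cluster = seq_len(100))
  expect_equal(gls$beta, ols$beta)
  expect_equal(gls$variance, ols$variance)

  # clustered noise, cluster-correlated regressor: OLS overstates z,
  # GLS stays near N(0, 1)
  zs <- replicate(300, {
    cl <- rep(1:150, each = 2)
    u <- rnorm(150)[cl]
    x <- (rnorm(150)[cl] + rnorm(300)) / sqrt(2)
    yy <- u * sqrt(0.8) + rnorm(300, 0, sqrt(0.2))
    c(famhist:::.linearFitGLS(yy, cbind(1, x), cl)$statistic,
      famhist:::.linearFit(yy, cbind(1, x))$statistic)
  })
  expect_lt(var(zs[1, ]), 1.25)        # GLS calibrated
  expect_gt(var(zs[2, ]), 1.25)        # naive OLS inflated
})

test_that("CC-GWAS uses the 1000 offspring and rejects permuted genotypes", {
  st <- fixtureStudy()
  res <- ccgwasTest(st$cohort, st$genotypes, st$phenotypes, "snp8")
  expect_equal(res@n, 1000)
  expect_true(res@converged)
  expect_equal(res@statistic, res@beta / sqrt(res@variance))

  # permuting genotypes within the offspring kills the association signal
  set.seed(45)
  G <- genotypes(st$genotypes)
  off <- as.character(offspringIds(st$cohort))
  p <- replicate(60, {
    Gp <- G
    Gp[off, "snp8"] <- sample(Gp[off, "snp8"])
    gt <- new("GenotypeTable", geno = Gp,
              variants = variantInfo(st$genotypes))
    ccgwasTest(st$cohort, gt, st$phenotypes, "snp8")@pvalue
  })
  expect_lt(mean(p < 0.05), 0.2)
})
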