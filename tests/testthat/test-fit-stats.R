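# Chi-square testing, fit indices, information criteria, and nested model
# comparison.

test_that("saturated fits get perfect fit statistics", {
  fit <- fitML(saturatedSpecification(observedNames(momDefault)), momDefault)
  ct <- chiSquareTest(fit)
  expect_equal(ct$chisq, 0, tolerance = 1e-8)
  expect_identical(ct$df, 0L)
  expect_equal(ct$pvalue, 1)
  fi <- fitIndices(fit)
  expect_equal(unname(fi), c(0, 0, 1, 1), tolerance = 1e-8)
})

test_that("chi-square scales linearly in n at fixed discrepancy", {
  tab <- hoSpecification(specDefault, "free", sds = momDefault)
  S <- momentsMatrix(momDefault)
  fit1 <- fitML(tab, sampleMoments(S, 180, divisor = "ml"))
  fit2 <- fitML(tab, sampleMoments(S, 360, divisor = "ml"))
  expect_equal(fit1@discrepancy, fit2@discrepancy, tolerance = 1e-9)
  expect_equal(2 * chiSquareTest(fit1)$chisq, chiSquareTest(fit2)$chisq,
               tolerance = 1e-7)
})

test_that("the log-likelihood matches a per-observation density sum", {
  ## independent oracle: sum of mean-centered multivariate-normal log
  ## densities at the implied covariance equals the closed-form logLik
  sim <- simulateSample(fx, 60, seed = 8)
  fit <- fitML(saturatedSpecification(observedNames(sim$moments)),
               sim$moments)
  X <- as.matrix(sim$data)
  Xc <- sweep(X, 2, colMeans(X))
  Sg <- impliedMatrix(fit)
  p <- ncol(X)
  direct <- sum(-0.5 * (p * log(2 * pi) +
                          as.numeric(determinant(Sg)$modulus) +
                          stats::mahalanobis(Xc, center = FALSE, cov = Sg)))
  expect_equal(as.numeric(logLik(fit)), direct, tolerance = 1e-8)
})

test_that("information criteria follow their penalty algebra", {
  fit <- cachedFit("free")
  ic <- informationCriteria(fit)
  q <- nFree(fit)
  n <- nobs(fit)
  expect_equal(unname(ic["aic"]), -2 * fit@logLik + 2 * q)
  expect_equal(unname(ic["bic"] - ic["aic"]), q * (log(n) - 2))
  expect_gt(ic["bic"], ic["aic"])  # ln 180 > 2
  expect_equal(unname(ic["sabic"]), -2 * fit@logLik + q * log((n + 2) / 24))
})

test_that("chi-square differences are additive over the nested sequence", {
  unit <- cachedFit("unit"); free <- cachedFit("free")
  relaxed <- cachedFit("relaxed")
  same <- chiSquareDifference(unit, unit)
  expect_equal(same$delta.chisq, 0)
  expect_identical(same$delta.df, 0L)
  expect_equal(same$pvalue, 1)

  d1 <- chiSquareDifference(unit, free)
  expect_identical(d1$delta.df, 3L)
  expect_equal(d1$delta.chisq,
               chiSquareTest(unit)$chisq - chiSquareTest(free)$chisq)
  d2 <- chiSquareDifference(free, relaxed)
  expect_identical(d2$delta.df, 5L)
  expect_equal(d2$delta.chisq,
               chiSquareTest(free)$chisq - chiSquareTest(relaxed)$chisq)
})

test_that("non-nested or misordered comparisons are rejected", {
  expect_error(chiSquareDifference(cachedFit("unit"), cachedFit("one_step")),
               "not nested|identical moments")
  expect_error(chiSquareDifference(cachedFit("free"), cachedFit("unit")),
               "not nested")
  other <- simulateSample(fx, 180, seed = 1234)$moments
  refit <- fitML(hoSpecification(specDefault, "free", sds = other), other)
  expect_error(chiSquareDifference(cachedFit("unit"), refit),
               "identical moments")
})

test_that("fit statistics are invariant to variable reordering", {
  perm <- c("colf", "age", "pH", "cover", "text", "dist", "mois")
  S <- momentsMatrix(momDefault)[perm, perm]
  momPerm <- sampleMoments(S, 180, divisor = "ml")
  tab <- hoSpecification(specDefault, "free", sds = momPerm)
  fitP <- fitML(tab, momPerm)
  fm1 <- fitMeasures(cachedFit("free"))
  fm2 <- fitMeasures(fitP)
  expect_equal(fm1, fm2, tolerance = 1e-7)
})

test_that("the chi-square test is calibrated under a correct model", {
  ## data generated from the fixture (cross-block covariances zero) lie in
  ## the relaxed model's parameter space, so n * F should be central
  ## chi-square with df = 3 and reject at about the nominal 5% rate
  reps <- 500
  n <- 180
  spec <- illustrativeSpec()
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    sim <- simulateSample(fx, n, seed = 20000 + r)
    fit <- tryCatch(
      suppressWarnings(fitML(hoSpecification(spec, "relaxed",
                                             sds = sim$moments),
                             sim$moments, se = FALSE)),
      error = function(e) NULL)
    if (is.null(fit) || !converged(fit)) { rej[r] <- NA; next }
    ct <- chiSquareTest(fit)
    expect_identical(ct$df, 3L)
    rej[r] <- ct$pvalue < 0.05
  }
  rate <- mean(rej, na.rm = TRUE)
  expect_gt(mean(!is.na(rej)), 0.95)
  expect_lt(abs(rate - 0.05), 0.03)
})
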