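# Maximum-likelihood estimation, weight recovery, standardized solutions,
# and delta-method standard errors.

test_that("a saturated model reproduces the sample moments with F = 0", {
  fit <- fitML(saturatedSpecification(observedNames(momDefault)), momDefault)
  expect_true(converged(fit))
  expect_lt(fit@discrepancy, 1e-10)
  expect_lt(max(abs(impliedMatrix(fit) - momentsMatrix(momDefault))), 1e-8)
})

test_that("the free-weight variant fitted to its own population is exact", {
  mom <- sampleMoments(populationCovariance(fx), 180, divisor = "ml")
  fit <- fitML(hoSpecification(illustrativeSpec(), "free", sds = mom), mom)
  expect_true(converged(fit))
  expect_lt(fit@discrepancy, 1e-12)
  expect_lt(max(abs(coef(fit) - trueValues(fx)[names(coef(fit))])), 1e-4)
  ## jittered starts land on the same optimum
  fit2 <- fitML(fit@table, mom, start = unname(coef(fit)) + 0.2)
  expect_lt(max(abs(coef(fit2) - coef(fit))), 1e-6)
})

test_that("weights are the first row of the inverted loading matrix", {
  expect_equal(weightsFromLoadings(diag(3)), setNames(c(1, 0, 0), NULL),
               ignore_attr = TRUE)
  set.seed(21)
  Lambda <- matrix(rnorm(16), 4, dimnames = list(paste0("x", 1:4), NULL))
  w <- weightsFromLoadings(Lambda)
  W <- attr(w, "W")
  expect_lt(max(abs(W %*% Lambda - diag(4))), 1e-10)
  expect_error(weightsFromLoadings(matrix(1, 3, 3)), "degenerate")
})

test_that("unit-weight fits recover weights of exactly one", {
  fit <- cachedFit("unit")
  w <- c(recoverWeights(fit, "Soil"), recoverWeights(fit, "Land"))
  expect_lt(max(abs(w - 1)), 1e-8)
})

test_that("weight standardization multiplies by the sd ratio", {
  expect_equal(standardizedWeights(1, 2, 4), 0.5)
  w <- c(a = 0.4, b = -1.2)
  expect_equal(standardizedWeights(w, c(1, 1), 1), w)
  expect_warning(out <- standardizedWeights(w, c(1, 1), -1), "Heywood")
  expect_true(all(is.na(out)))
  ## fitted standardized weights match the direct covariance-based formula
  fit <- cachedFit("free")
  bw <- blockWeights(fit, se = FALSE)
  S <- momentsMatrix(momDefault)
  for (b in fit@table@blocks) {
    w <- recoverWeights(fit, b$name)
    sdC <- sqrt(drop(t(w) %*% S[b$components, b$components] %*% w))
    direct <- standardizedWeights(w, sqrt(diag(S)[b$components]), sdC)
    got <- bw$weight.std[bw$block == b$name]
    expect_equal(got, direct, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("standardization leaves unit-variance solutions unchanged", {
  ## saturated fit to a correlation matrix: implied variances are all 1
  S <- momentsMatrix(momDefault)
  R <- stats::cov2cor(S)
  mom <- sampleMoments(R, 180, divisor = "ml")
  fit <- fitML(saturatedSpecification(colnames(R)), mom)
  std <- standardizedSolution(fit, se = FALSE)
  expect_equal(std$est.std, std$est, tolerance = 1e-8)
})

test_that("population-level standardized paths are recovered within 1e-4", {
  mom <- sampleMoments(populationCovariance(fx), 180, divisor = "ml")
  fit <- fitML(hoSpecification(illustrativeSpec(), "free", sds = mom), mom)
  std <- stdOf(fit)
  pop <- populationStandardizedSolution(fx)
  want <- pop$est.std[match(structuralPathLabels, pop$label)]
  expect_lt(max(abs(std - want)), 1e-4)
  ## standardized covariances are correlations
  full <- standardizedSolution(fit, se = FALSE)
  cv <- full$est.std[full$role == "covariance"]
  expect_true(all(abs(cv) <= 1 + 1e-10))
})

test_that("standard errors are positive and match a parametric bootstrap", {
  fit <- cachedFit("free")
  expect_true(all(standardErrors(fit) > 0))
  bw <- blockWeights(fit, se = TRUE)
  expect_true(all(bw$se > 0))

  ## parametric bootstrap: resample from the fitted model at n = 180,
  ## refit, recover weights; the delta-method SE of each free weight
  ## should agree with the bootstrap spread within 15%
  B <- 300
  n <- 180
  spec <- illustrativeSpec()
  wboot <- matrix(NA_real_, B, 5)
  for (r in seq_len(B)) {
    sim <- simulateSample(impliedMatrix(fit), n, seed = 5000 + r)
    bfit <- tryCatch(
      suppressWarnings(fitML(hoSpecification(spec, "free",
                                             sds = sim$moments),
                             sim$moments, se = FALSE)),
      error = function(e) NULL)
    if (is.null(bfit) || !converged(bfit)) next
    wboot[r, ] <- c(recoverWeights(bfit, "Soil"),
                    recoverWeights(bfit, "Land"))
  }
  keep <- stats::complete.cases(wboot)
  expect_gt(mean(keep), 0.9)
  bootSE <- apply(wboot[keep, ], 2, stats::sd)
  deltaSE <- bw$se
  expect_true(all(abs(deltaSE / bootSE - 1) < 0.15))
})

test_that("chi-square is monotone over the nested variant sequence", {
  cu <- chiSquareTest(cachedFit("unit"))$chisq
  cf <- chiSquareTest(cachedFit("free"))$chisq
  cr <- chiSquareTest(cachedFit("relaxed"))$chisq
  expect_gte(cu, cf - 1e-8)
  expect_gte(cf, cr - 1e-8)
})

test_that("degenerate inputs are rejected or flagged, not silently accepted", {
  S <- momentsMatrix(momDefault)
  bad <- S; bad[1, 1] <- -1
  expect_error(fitML(saturatedSpecification(colnames(S)),
                     sampleMoments(bad, 180, "ml")),
               "positive definite")
  tiny <- sampleMoments(S, 5, divisor = "ml")
  expect_warning(fitML(saturatedSpecification(colnames(S)), tiny),
                 "sample size")
  ## iteration-limit hit: flag goes down, no exception
  fit <- suppressWarnings(
    fitML(hoSpecification(specDefault, "free", sds = momDefault),
          momDefault,
          control = list(iter.max = 1, eval.max = 3, maxPolish = 0,
                         retries = 0)))
  expect_s4_class(fit, "FitResult")
  expect_false(converged(fit))
})

test_that("unbiased input moments are rescaled to the ml convention", {
  S <- momentsMatrix(momDefault)
  n <- 180
  unb <- sampleMoments(S * n / (n - 1), n, divisor = "unbiased")
  fit1 <- fitML(hoSpecification(specDefault, "free", sds = momDefault),
                momDefault)
  fit2 <- fitML(hoSpecification(specDefault, "free", sds = momDefault), unb)
  expect_equal(fit1@discrepancy, fit2@discrepancy, tolerance = 1e-9)
  expect_identical(fit2@moments@divisor, "ml")
})
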