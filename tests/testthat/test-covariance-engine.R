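# Mapping parameter tables to model-implied covariance matrices, the
# two-step score reduction, and the numerical identification check.

test_that("effects-coding constraints resolve to the remaining loading", {
  spec <- modelSpec(c("x1", "x2", "x3", "y"),
                    blocks = list(compositeBlock("C", c("x1", "x2", "x3"))),
                    paths = list(c("C", "y")))
  tab <- hoSpecification(spec, "free")
  theta <- setNames(numeric(nFree(tab)), freeLabels(tab))
  theta["C=~x1"] <- 0.2
  theta["C=~x2"] <- 0.3
  theta[c("C~~C", "nu1_C~~nu1_C", "nu2_C~~nu2_C", "y~~y")] <- 1
  res <- resolveConstraints(tab, theta)
  expect_equal(res$B["x3", "C"], 0.5)  # 1 - 0.2 - 0.3
  ## unit variant: excrescent loading pair is (1, -1), sum 0
  tabU <- hoSpecification(spec, "unit")
  resU <- resolveConstraints(tabU, rep(1, nFree(tabU)))
  expect_equal(resU$B["x2", "nu1_C"] + resU$B["x1", "nu1_C"], 0)
  expect_equal(sort(c(resU$B["x2", "nu1_C"], resU$B["x1", "nu1_C"])),
               c(-1, 1))
})

test_that("an all-fixed table accepts an empty theta", {
  pars <- data.frame(
    lhs = c("a", "b", "a"), rhs = c("a", "b", "b"),
    role = c("variance", "variance", "covariance"),
    status = "fixed", value = c(1, 1, 0.5), expr = NA_character_,
    start = NA_real_, label = c("a~~a", "b~~b", "a~~b"))
  tab <- new("ParameterTable", pars = pars, variables = c("a", "b"),
             observed = c("a", "b"), blocks = list(), variant = "fixed",
             meta = list())
  res <- resolveConstraints(tab, numeric())
  expect_equal(res$Psi, matrix(c(1, .5, .5, 1), 2,
                               dimnames = list(c("a", "b"), c("a", "b"))))
  id <- checkLocalIdentification(tab, theta0 = numeric())
  expect_identical(id$rank, 0L)
  expect_true(id$identified)
})

test_that("implied covariance follows path-tracing algebra", {
  expect_equal(impliedCovariance(matrix(0, 3, 3), diag(3)), diag(3))
  ## single path b from an exogenous variable: var(y) = b^2 phi + psi
  b <- 0.7; phi <- 2; psi <- 0.3
  B <- matrix(c(0, b, 0, 0), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  Psi <- diag(c(phi, psi)); dimnames(Psi) <- dimnames(B)
  S <- impliedCovariance(B, Psi)
  expect_equal(S["y", "y"], b^2 * phi + psi)
  expect_equal(S["x", "y"], b * phi)
  ## cyclic model: singular I - B
  Bc <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(impliedCovariance(Bc, diag(2)), "cyclic")
})

test_that("implied covariance is symmetric over random admissible parameters", {
  tab <- fx@table
  q <- nFree(tab)
  set.seed(7)
  for (i in 1:20) {
    theta <- unname(trueValues(fx)) + 0.2 * rnorm(q)
    Sg <- impliedMoments(tab, theta)
    expect_identical(Sg, t(Sg))
  }
})

test_that("implied covariance matches a large-sample simulation", {
  Sg <- populationCovariance(fx)
  n <- 1e6
  sim <- simulateSample(fx, n, seed = 99)
  S <- momentsMatrix(sim$moments)
  ## Monte-Carlo standard error of a normal covariance estimate
  mcse <- sqrt((outer(diag(Sg), diag(Sg)) + Sg^2) / n)
  expect_true(all(abs(S - Sg) <= 3 * mcse))
})

test_that("fitted H-O models replicate the component covariance block exactly", {
  S <- momentsMatrix(momDefault)
  for (v in c("unit", "free", "relaxed")) {
    fit <- cachedFit(v)
    for (b in fit@table@blocks) {
      cc <- b$components
      expect_lt(max(abs(impliedMatrix(fit)[cc, cc] - S[cc, cc])), 1e-6)
    }
  }
})

test_that("implied composite-excrescent covariances are exactly zero", {
  fit <- cachedFit("free")
  res <- resolveConstraints(fit@table, unname(coef(fit)))
  Cfull <- impliedCovariance(res$B, res$Psi)
  for (b in fit@table@blocks)
    for (nu in b$excrescent)
      expect_equal(Cfull[b$name, nu], 0)
})

test_that("two-step reduction computes composite-score moments", {
  S <- matrix(c(1, .5, 0, .5, 1, 0, 0, 0, 2), 3,
              dimnames = list(c("x1", "x2", "z"), c("x1", "x2", "z")))
  mom <- sampleMoments(S, 100, divisor = "ml")
  red <- twoStepReduce(mom, list(compositeBlock("C", c("x1", "x2"))))
  expect_equal(momentsMatrix(red)["C", "C"], 3)     # 1 + 1 + 2 * 0.5
  expect_equal(momentsMatrix(red)["z", "z"], 2)     # passthrough unchanged
  expect_equal(momentsMatrix(red)["C", "z"], 0)
  expect_identical(red@n, 100)
  expect_error(twoStepReduce(mom, list(compositeBlock("C", c("x1", "bad")))),
               "unknown variable")
})

test_that("two-step reduction is linear in the input moments", {
  set.seed(3)
  A1 <- crossprod(matrix(rnorm(49), 7))
  A2 <- crossprod(matrix(rnorm(49), 7))
  nm <- observedNames(specDefault)
  dimnames(A1) <- dimnames(A2) <- list(nm, nm)
  a <- 0.3; b <- 1.7
  r <- function(M) momentsMatrix(twoStepReduce(sampleMoments(M, 10, "ml"),
                                               specDefault))
  expect_equal(r(a * A1 + b * A2), a * r(A1) + b * r(A2))
})

test_that("local identification holds at the fixture and fails without rule 5", {
  id <- checkLocalIdentification(fx@table, theta0 = unname(trueValues(fx)))
  expect_identical(id$rank, id$q)
  expect_true(id$identified)

  ## removing the free-weight composite's only structural neighbor makes
  ## the composite loadings unidentified
  spec <- modelSpec(c("x1", "x2", "x3", "y"),
                    blocks = list(compositeBlock("C", c("x1", "x2", "x3"))),
                    paths = list(c("C", "y")))
  tab <- hoSpecification(spec, "free")
  tab@pars <- tab@pars[tab@pars$label != "y~C", ]
  id2 <- checkLocalIdentification(tab)
  expect_lt(id2$rank, id2$q)
  expect_true(any(grepl("C=~", id2$nullLabels)))
})
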