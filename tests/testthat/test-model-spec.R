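# Declarative model description and construction of identified parameter
# tables for the H-O variants and the one-step/two-step baselines.

test_that("composite blocks enforce the excrescent-variable rules", {
  expect_error(compositeBlock("S", "x1"), "at least 2")
  expect_error(compositeBlock("S", c("x1", "x2", "x3"),
                              references = c("x2", "x2")), "twice")
  expect_error(compositeBlock("S", c("x1", "x2", "x3"), shared = "x1",
                              references = c("x1", "x2")),
               "shared component cannot also be a reference")
  b <- compositeBlock("S", c("x1", "x2", "x3"))
  expect_identical(b@shared, "x1")
  expect_identical(b@references, c("x2", "x3"))
})

test_that("model specs reject inconsistent declarations", {
  expect_error(modelSpec(c("a", "b"),
                         blocks = list(compositeBlock("S", c("a", "b")),
                                       compositeBlock("T", c("b", "a")))),
               "disjoint")
  expect_error(modelSpec(c("a", "b", "c"),
                         paths = list(c("a", "c"), c("c", "a"))),
               "acyclic")
  expect_error(modelSpec("a", latents = data.frame(
    name = "L", indicator = "a", reliability = 1.2)), "reliabilit")
})

test_that("H-O tables implement the identification rules for every variant", {
  sds <- sqrt(diag(momentsMatrix(momDefault)))
  qExpected <- c(unit = 17, free = 20, relaxed = 25)
  dfExpected <- c(unit = 11, free = 8, relaxed = 3)
  for (v in names(qExpected)) {
    tab <- hoSpecification(specDefault, v, sds = sds)
    pars <- parameterRows(tab)
    expect_identical(nFree(tab), as.integer(qExpected[v]))
    expect_identical(countDegreesOfFreedom(tab), as.integer(dfExpected[v]))
    for (b in tab@blocks) {
      k <- length(b$components)
      expect_length(b$excrescent, k - 1L)
      for (nu in b$excrescent) {
        ld <- pars[pars$role == "loading" & pars$lhs == nu, ]
        expect_identical(nrow(ld), 2L)  # exactly two nonzero loadings
        ref <- ld[ld$status == "fixed" & ld$value == 1, ]
        expect_identical(nrow(ref), 1L)
        # Rule 4: cov(composite, own excrescent) present and fixed to 0
        r4 <- pars[pars$role == "covariance" &
                     ((pars$lhs == b$name & pars$rhs == nu) |
                        (pars$lhs == nu & pars$rhs == b$name)), ]
        expect_identical(nrow(r4), 1L)
        expect_identical(r4$status, "fixed")
        expect_identical(r4$value, 0)
      }
      ## component error variances fixed to 0
      ev <- pars[pars$role == "variance" & pars$lhs %in% b$components, ]
      expect_true(all(ev$status == "fixed" & ev$value == 0))
      ## unit variant: excrescent loadings fixed at +1/-1 (sum-to-zero)
      if (v == "unit") {
        sh <- pars[pars$role == "loading" & pars$lhs %in% b$excrescent &
                     pars$rhs == b$shared, ]
        expect_true(all(sh$status == "fixed" & sh$value == -1))
      }
    }
  }
  ## q arithmetic between the variants
  expect_identical(qExpected[["unit"]] + 3, qExpected[["free"]])
  expect_identical(qExpected[["free"]] + 5, qExpected[["relaxed"]])
})

test_that("relaxed variant frees exactly the cross-block covariances", {
  tab <- hoSpecification(specDefault, "relaxed",
                         sds = sqrt(diag(momentsMatrix(momDefault))))
  free <- hoSpecification(specDefault, "free",
                          sds = sqrt(diag(momentsMatrix(momDefault))))
  extra <- setdiff(freeLabels(tab), freeLabels(free))
  expect_setequal(extra, c("nu1_Soil~~nu1_Land", "nu2_Soil~~nu1_Land",
                           "nu1_Soil~~Land", "nu2_Soil~~Land",
                           "Soil~~nu1_Land"))
})

test_that("free-parameter count is invariant to shared/reference choice", {
  for (v in c("unit", "free", "relaxed")) {
    t1 <- hoSpecification(specDefault, v, sds = momDefault)
    t2 <- hoSpecification(specAltSharing, v, sds = momDefault)
    expect_identical(nFree(t1), nFree(t2))
    expect_identical(countDegreesOfFreedom(t1), countDegreesOfFreedom(t2))
    ## ... but the row patterns differ
    if (v != "unit")
      expect_false(setequal(freeLabels(t1), freeLabels(t2)))
  }
  for (sc in c("reference", "variance_standardization")) {
    t3 <- hoSpecification(specDefault, "free", sds = momDefault,
                          scaling = sc)
    expect_identical(nFree(t3), 20L)
  }
})

test_that("a free-weight composite needs a structural neighbor (rule 5)", {
  lonely <- modelSpec(c("x1", "x2", "x3", "y"),
                      blocks = list(compositeBlock("C", c("x1", "x2", "x3"))),
                      paths = NULL)
  expect_error(hoSpecification(lonely, "free"), "identification")
  ## unit-weight composites do not need a neighbor
  expect_s4_class(hoSpecification(lonely, "unit"), "ParameterTable")
})

test_that("one-step tables fix composite disturbances and reject composite covariances", {
  spec1 <- illustrativeSpec(soilLandCovariance = FALSE)
  tab <- oneStepSpecification(spec1, sds = momDefault)
  expect_identical(nFree(tab), 25L)
  expect_identical(countDegreesOfFreedom(tab), 3L)
  pars <- parameterRows(tab)
  dist <- pars[pars$role == "variance" & pars$lhs %in% c("Soil", "Land"), ]
  expect_true(all(dist$status == "fixed" & dist$value == 0))
  ## the last declared component sets the composite's scale by default
  wfix <- pars[pars$role == "path" & pars$rhs == "Soil" &
                 pars$status == "fixed", ]
  expect_identical(wfix$lhs, "pH")
  ## all 15 component moments free
  comps <- c("text", "mois", "pH", "age", "dist")
  cv <- pars[pars$lhs %in% comps & pars$rhs %in% comps, ]
  expect_identical(sum(cv$status == "free"), 15L)
  expect_error(oneStepSpecification(specDefault, sds = momDefault),
               "not possible to specify a covariance")
  expect_error(oneStepSpecification(spec1, sds = momDefault,
                                    fixWeights = c(Land = NA)),
               "scale")
})

test_that("the reliability formula fixes error variances", {
  expect_equal(fixedErrorVariance(0.9, 0.3017), 0.009102, tolerance = 5e-5)
  expect_equal(fixedErrorVariance(0.9, 0.3017), (1 - 0.9) * 0.3017^2)
  expect_equal(fixedErrorVariance(0.9, 0.1867), 0.003486, tolerance = 5e-4)
  expect_identical(fixedErrorVariance(1.0, 7.3), 0)
  expect_error(fixedErrorVariance(0, 1), "reliability")
  expect_error(fixedErrorVariance(1.1, 1), "reliability")
  expect_error(fixedErrorVariance(0.9, -1), "positive")
})

test_that("degrees of freedom guard against over-parameterization", {
  sat <- saturatedSpecification(c("a", "b", "c"))
  expect_identical(countDegreesOfFreedom(sat), 0L)
  expect_error(countDegreesOfFreedom(sat, p = 2), "over-parameterized")
})

test_that("parameter tables round-trip through CSV", {
  tab <- hoSpecification(specDefault, "unit", sds = momDefault)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  writeParameterTable(tab, path)
  back <- readParameterTable(path, observed = observedNames(specDefault))
  expect_identical(freeLabels(back), freeLabels(tab))
  expect_identical(nFree(back), nFree(tab))
  ## the re-read table resolves to the same matrices
  theta <- rep(0.5, nFree(tab))
  r1 <- resolveConstraints(tab, theta)
  r2 <- resolveConstraints(back, theta)
  expect_equal(r1$B[tab@variables, tab@variables],
               r2$B[tab@variables, tab@variables])
  expect_equal(r1$Psi[tab@variables, tab@variables],
               r2$Psi[tab@variables, tab@variables])
})
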