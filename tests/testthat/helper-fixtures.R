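# Shared fixtures: the population model, one simulated sample (n = 180,
# fixed seed), and lazily cached fits of the main variants on that sample.

fx <- illustrativeFixture()
specDefault <- illustrativeSpec()
simDefault <- simulateSample(fx, 180, seed = 42)
momDefault <- simDefault$moments

.fitCache <- new.env(parent = emptyenv())

cachedFit <- function(variant) {
  if (!is.null(.fitCache[[variant]])) return(.fitCache[[variant]])
  fit <- switch(variant,
    one_step = fitML(oneStepSpecification(
      illustrativeSpec(soilLandCovariance = FALSE), sds = momDefault),
      momDefault),
    two_step = {
      red <- twoStepReduce(momDefault, specDefault)
      fitML(twoStepSpecification(specDefault, sds = red), red)
    },
    fitML(hoSpecification(specDefault, variant, sds = momDefault),
          momDefault))
  .fitCache[[variant]] <- fit
  fit
}

## alternative shared/reference assignment of the same model
specAltSharing <- modelSpec(
  observed = observedNames(specDefault),
  blocks = list(
    compositeBlock("Soil", c("text", "mois", "pH"), shared = "mois",
                   references = c("pH", "text")),
    compositeBlock("Land", c("age", "dist"), shared = "dist",
                   references = "age")),
  latents = specDefault@latents, paths = specDefault@paths,
  covariances = specDefault@covariances)

structuralPathLabels <- c("Comp~Soil", "Colo~Soil", "Comp~Land",
                          "Colo~Land", "Colo~Comp")

stdOf <- function(fit, labels = structuralPathLabels, se = FALSE) {
  std <- standardizedSolution(fit, se = se)
  out <- std$est.std[match(labels, std$label)]
  names(out) <- labels
  out
}
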