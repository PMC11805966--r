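## Population-model construction and multivariate-normal sampling, so that
## every estimation path is testable without external data.  The built-in
## fixture emulates the structure of the forest-herb colonization example
## of Grace & Bollen (2008): two composite blocks, two single-indicator
## latent variables with reliability 0.9, and a saturated structural model.

#' The seven-variable example model
#'
#' Two composite blocks -- Soil built from soil texture (`text`), moisture
#' (`mois`) and pH, and Land built from stand age (`age`) and distance to
#' the colonization source (`dist`) -- plus two single-indicator latent
#' variables, competitor abundance (`Comp`, indicator `cover`) and
#' colonization frequency (`Colo`, indicator `colf`), each with an assumed
#' reliability of 0.9.  The structural model is saturated: both composites
#' affect both latents, Comp affects Colo, and Soil covaries with Land.
#'
#' @param variant default specification variant stored on the spec.
#' @param soilLandCovariance include the Soil ~~ Land covariance (drop it
#'   for the one-step baseline, where a covariance between two dependent
#'   composites cannot be specified).
#' @return a [ModelSpec-class].
#' @export
illustrativeSpec <- function(variant = "free", soilLandCovariance = TRUE) {
  modelSpec(
    observed = c("text", "mois", "pH", "age", "dist", "cover", "colf"),
    blocks = list(
      compositeBlock("Soil", c("text", "mois", "pH")),
      compositeBlock("Land", c("age", "dist"))),
    latents = data.frame(name = c("Comp", "Colo"),
                         indicator = c("cover", "colf"),
                         reliability = c(0.9, 0.9)),
    paths = list(c("Soil", "Comp"), c("Soil", "Colo"),
                 c("Land", "Comp"), c("Land", "Colo"),
                 c("Comp", "Colo")),
    covariances = if (soilLandCovariance) list(c("Soil", "Land")),
    variant = variant)
}

## documented true values of the fixture; unequal Soil loadings make the
## free- and unit-weight variants distinguishable
fixtureTruth <- c(
  "Soil=~text" = 0.20, "Soil=~mois" = 0.50,          # pH loading: 0.30
  "nu1_Soil=~text" = -0.80, "nu2_Soil=~text" = -1.20,
  "Soil~~Soil" = 1.00,
  "nu1_Soil~~nu1_Soil" = 0.50, "nu2_Soil~~nu2_Soil" = 0.40,
  "nu1_Soil~~nu2_Soil" = 0.10,
  "Land=~age" = 0.70,                                 # dist loading: 0.30
  "nu1_Land=~age" = -0.90,
  "Land~~Land" = 1.00, "nu1_Land~~nu1_Land" = 0.60,
  "Soil~~Land" = 0.30,
  "Comp~~Comp" = 0.50, "Colo~~Colo" = 0.40,
  "Comp~Soil" = 0.40, "Colo~Soil" = -0.20,
  "Comp~Land" = 0.25, "Colo~Land" = -0.35,
  "Colo~Comp" = -0.30)

#' Population fixture emulating the illustrative example
#'
#' A free-weight H-O population model over the seven variables of
#' [illustrativeSpec()], with documented true values (unequal composite
#' loadings, so unit weights are misspecified) and indicator error
#' variances chosen self-consistently so that the reliability of `cover`
#' and `colf` is exactly 0.9: var(error) = var(latent)/9, which equals
#' (1 - 0.9) times the implied indicator variance.
#'
#' @return a [PopulationModel-class]; its implied 7 x 7 covariance matrix
#'   is positive definite.
#' @export
illustrativeFixture <- function() {
  spec <- illustrativeSpec("free")
  tmp <- hoSpecification(spec, "free", sds = c(cover = 1, colf = 1))
  theta <- fixtureTruth[freeLabels(tmp)]
  stopifnot(!anyNA(theta))
  cm <- compileTable(tmp)
  ev <- evalModel(cm, unname(theta))
  varComp <- ev$Cfull[match("Comp", cm$vars), match("Comp", cm$vars)]
  varColo <- ev$Cfull[match("Colo", cm$vars), match("Colo", cm$vars)]
  ## rel = 0.9 exactly: var(indicator) = var(latent) * 10/9
  sds <- c(cover = sqrt(varComp * 10 / 9), colf = sqrt(varColo * 10 / 9))
  tab <- hoSpecification(spec, "free", sds = sds)
  sigma <- impliedMoments(tab, unname(theta))
  new("PopulationModel", table = tab, theta = theta, sigma = sigma,
      spec = spec)
}

#' Standardized solution at the population values
#'
#' @param model a [PopulationModel-class].
#' @return data.frame as from [standardizedSolution()], evaluated at the
#'   true parameter values (no standard errors).
#' @export
populationStandardizedSolution <- function(model) {
  stopifnot(is(model, "PopulationModel"))
  stdCore(model@table)$frame(unname(model@theta))
}

#' Simulate multivariate-normal data from a population model
#'
#' @param model a [PopulationModel-class], or a positive-definite named
#'   covariance matrix.
#' @param n number of observations (>= 2).
#' @param seed optional seed; sampling is reproducible given the seed and
#'   the global RNG state is restored afterwards.
#' @return list with `data` (n x p data.frame) and `moments` (a
#'   [SampleMoments-class] on the divisor-n convention).
#' @export
simulateSample <- function(model, n, seed = NULL) {
  sigma <- if (is(model, "PopulationModel")) model@sigma else as.matrix(model)
  stopifnot(n >= 2, !is.null(colnames(sigma)))
  p <- ncol(sigma)
  if (n < p)
    warning(sprintf("n = %d below the number of variables (%d): sample moments will be singular",
                    n, p))
  X <- withSeed(seed, MASS::mvrnorm(n, mu = rep(0, p), Sigma = sigma))
  colnames(X) <- colnames(sigma)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  list(data = as.data.frame(X),
       moments = sampleMoments(S, n, divisor = "ml"))
}

## per-replicate seeds derived deterministically from the master seed
replicateSeed <- function(seed, r) (seed + 7919 * r) %% 2147483629

#' Monte-Carlo parameter recovery study
#'
#' Repeatedly simulates samples from a population model, fits the requested
#' H-O variant, and summarizes bias, root-mean-square error and (optionally)
#' 95% confidence-interval coverage of the standardized structural paths,
#' plus recovery of the composite weights.  Free-weight recovery is judged
#' on the sum-to-one normalized scale (the scale fixing leaves an overall
#' factor undetermined); unit-weight recovery is judged on the raw scale,
#' where the truth is exactly 1.  Non-converged replicates are counted and
#' excluded.
#'
#' @param model a [PopulationModel-class].
#' @param variant `"free"`, `"unit"`, or `"relaxed"`.
#' @param n sample size per replicate.
#' @param reps number of replicates (>= 2).
#' @param seed master seed; per-replicate seeds are derived
#'   deterministically.
#' @param coverage compute delta-method confidence-interval coverage
#'   (slower; needs standard errors per replicate).
#' @param level confidence level for the coverage column.
#' @return object of class `recoveryStudy`: `paths` and `weights`
#'   data.frames with columns `truth`, `mean`, `bias`, `rmse` (and
#'   `coverage` for paths), plus `nConverged`, `reps`, `n`, `variant`.
#' @export
recoveryStudy <- function(model, variant = c("free", "unit", "relaxed"),
                          n, reps, seed = 1, coverage = TRUE, level = 0.95) {
  stopifnot(is(model, "PopulationModel"), reps >= 2)
  variant <- match.arg(variant)
  spec <- model@spec

  pop <- populationStandardizedSolution(model)
  pathRows <- pop$role == "path" & pop$status == "free" &
    !(pop$lhs %in% specComponents(spec))
  pathLabels <- pop$label[pathRows]
  truthStd <- setNames(pop$est.std[pathRows], pathLabels)

  blocks <- model@table@blocks
  truthW <- list()
  for (b in blocks) {
    if (variant == "unit") truthW[[b$name]] <-
        setNames(rep(1, length(b$components)), b$components)
    else {
      cm <- compileTable(model@table)
      ev <- evalModel(cm, unname(model@theta))
      Lambda <- ev$B[match(b$components, cm$vars),
                     match(c(b$name, b$excrescent), cm$vars), drop = FALSE]
      rownames(Lambda) <- b$components
      w <- weightsFromLoadings(Lambda)
      truthW[[b$name]] <- w / sum(w)
    }
  }

  z <- stats::qnorm(1 - (1 - level) / 2)
  estP <- seP <- matrix(NA_real_, reps, length(pathLabels),
                        dimnames = list(NULL, pathLabels))
  wNames <- unlist(lapply(blocks, function(b)
    paste0(b$name, ".", b$components)), use.names = FALSE)
  estW <- matrix(NA_real_, reps, length(wNames),
                 dimnames = list(NULL, wNames))
  ok <- logical(reps)

  for (r in seq_len(reps)) {
    sim <- simulateSample(model, n, seed = replicateSeed(seed, r))
    fit <- tryCatch({
      tab <- hoSpecification(spec, variant, sds = sim$moments)
      ## Heywood warnings at small n are recorded via convergence, not fatal
      suppressWarnings(fitML(tab, sim$moments, se = coverage))
    }, error = function(e) NULL)
    if (is.null(fit) || !converged(fit)) next
    ok[r] <- TRUE
    std <- suppressWarnings(standardizedSolution(fit, se = coverage))
    idx <- match(pathLabels, std$label)
    estP[r, ] <- std$est.std[idx]
    if (coverage) seP[r, ] <- std$se.std[idx]
    for (b in blocks) {
      w <- recoverWeights(fit, b$name)
      if (variant != "unit") w <- w / sum(w)
      estW[r, paste0(b$name, ".", b$components)] <- w
    }
  }

  nC <- sum(ok)
  if (nC < 2) stop("fewer than 2 converged replicates")
  estP <- estP[ok, , drop = FALSE]
  seP <- seP[ok, , drop = FALSE]
  estW <- estW[ok, , drop = FALSE]

  paths <- data.frame(
    label = pathLabels,
    truth = unname(truthStd),
    mean = colMeans(estP),
    bias = colMeans(estP) - unname(truthStd),
    rmse = sqrt(colMeans(sweep(estP, 2, truthStd)^2)),
    coverage = if (coverage)
      colMeans(abs(sweep(estP, 2, truthStd)) <= z * seP) else NA_real_,
    row.names = NULL)

  truthWvec <- unlist(truthW, use.names = FALSE)
  weights <- data.frame(
    label = wNames,
    truth = truthWvec,
    mean = colMeans(estW),
    bias = colMeans(estW) - truthWvec,
    rmse = sqrt(colMeans(sweep(estW, 2, truthWvec)^2)),
    row.names = NULL)

  structure(list(paths = paths, weights = weights, nConverged = nC,
                 reps = reps, n = n, variant = variant),
            class = "recoveryStudy")
}

#' @export
print.recoveryStudy <- function(x, digits = 4, ...) {
  cat(sprintf("Recovery study: variant '%s', n = %d, %d/%d replicates converged\n",
              x$variant, x$n, x$nConverged, x$reps))
  cat("\nStandardized structural paths:\n")
  print(cbind(x$paths[1], round(x$paths[-1], digits)), row.names = FALSE)
  cat("\nComposite weights",
      if (x$variant == "unit") "(raw scale)" else "(sum-to-one scale)", ":\n")
  print(cbind(x$weights[1], round(x$weights[-1], digits)), row.names = FALSE)
  invisible(x)
}
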