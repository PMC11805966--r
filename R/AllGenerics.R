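#' @importFrom stats coef vcov logLik nobs
NULL

#' Number of free parameters
#'
#' @param object a [ParameterTable-class] or [FitResult-class].
#' @return integer count of free labels (q).
#' @export
setGeneric("nFree", function(object) standardGeneric("nFree"))

#' @rdname nFree
setMethod("nFree", "ParameterTable", function(object)
  sum(object@pars$status == "free"))

#' @rdname nFree
setMethod("nFree", "FitResult", function(object) nFree(object@table))

#' Free-parameter labels
#'
#' @param object a [ParameterTable-class].
#' @return character vector of free labels in table order.
#' @export
setGeneric("freeLabels", function(object) standardGeneric("freeLabels"))

#' @rdname freeLabels
setMethod("freeLabels", "ParameterTable", function(object)
  object@pars$label[object@pars$status == "free"])

#' Parameter rows of a table
#'
#' @param object a [ParameterTable-class] or [FitResult-class].
#' @return the underlying data.frame of parameter rows.
#' @export
setGeneric("parameterRows", function(object) standardGeneric("parameterRows"))

#' @rdname parameterRows
setMethod("parameterRows", "ParameterTable", function(object) object@pars)

#' @rdname parameterRows
setMethod("parameterRows", "FitResult", function(object) object@table@pars)

#' Observed-variable names
#'
#' @param object a model object.
#' @return character vector of observed variable names.
#' @export
setGeneric("observedNames", function(object) standardGeneric("observedNames"))

#' @rdname observedNames
setMethod("observedNames", "ParameterTable", function(object) object@observed)

#' @rdname observedNames
setMethod("observedNames", "SampleMoments", function(object) colnames(object@S))

#' @rdname observedNames
setMethod("observedNames", "ModelSpec", function(object) object@observed)

#' @rdname observedNames
setMethod("observedNames", "PopulationModel", function(object)
  object@table@observed)

#' Covariance matrix of sample moments
#'
#' @param object a [SampleMoments-class] or [PopulationModel-class].
#' @return the covariance matrix.
#' @export
setGeneric("momentsMatrix", function(object) standardGeneric("momentsMatrix"))

#' @rdname momentsMatrix
setMethod("momentsMatrix", "SampleMoments", function(object) object@S)

#' Population covariance matrix
#'
#' @param object a [PopulationModel-class].
#' @return the implied population covariance of the observed variables.
#' @export
setGeneric("populationCovariance",
           function(object) standardGeneric("populationCovariance"))

#' @rdname populationCovariance
setMethod("populationCovariance", "PopulationModel", function(object)
  object@sigma)

#' True parameter values of a population model
#'
#' @param object a [PopulationModel-class].
#' @return named numeric vector of true free-parameter values.
#' @export
setGeneric("trueValues", function(object) standardGeneric("trueValues"))

#' @rdname trueValues
setMethod("trueValues", "PopulationModel", function(object) object@theta)

#' @describeIn FitResult free-parameter estimates.
#' @param object a [FitResult-class].
#' @export
setMethod("coef", "FitResult", function(object, ...) object@estimates)

#' @describeIn FitResult estimated covariance matrix of the free parameters.
#' @export
setMethod("vcov", "FitResult", function(object, ...) object@vcovTheta)

#' @describeIn FitResult normal-theory log-likelihood at the optimum.
#' @export
setMethod("logLik", "FitResult", function(object, ...) {
  ll <- object@logLik
  attr(ll, "df") <- nFree(object)
  attr(ll, "nobs") <- object@moments@n
  class(ll) <- "logLik"
  ll
})

#' @describeIn FitResult sample size of the fitted moments.
#' @export
setMethod("nobs", "FitResult", function(object, ...) object@moments@n)

#' Standard errors of the free parameters
#'
#' @param object a [FitResult-class].
#' @return named numeric vector of expected-information standard errors.
#' @export
setGeneric("standardErrors", function(object) standardGeneric("standardErrors"))

#' @rdname standardErrors
setMethod("standardErrors", "FitResult", function(object) object@se)

#' Model-implied covariance matrix of a fit
#'
#' @param object a [FitResult-class].
#' @return implied covariance matrix of the observed variables.
#' @export
setGeneric("impliedMatrix", function(object) standardGeneric("impliedMatrix"))

#' @rdname impliedMatrix
setMethod("impliedMatrix", "FitResult", function(object) object@implied)

#' Convergence flag of a fit
#'
#' @param object a [FitResult-class].
#' @return logical.
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname converged
setMethod("converged", "FitResult", function(object) object@converged)

setMethod("show", "CompositeBlock", function(object) {
  cat(sprintf("CompositeBlock '%s' (%s weights): %s\n", object@name,
              object@weightMode, paste(object@components, collapse = ", ")))
  cat(sprintf("  shared: %s; references: %s\n", object@shared,
              paste(object@references, collapse = ", ")))
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %d observed, %d block(s), %d latent(s), %d path(s), %d covariance(s); variant '%s'\n",
              length(object@observed), length(object@blocks),
              nrow(object@latents), nrow(object@paths),
              nrow(object@covariances), object@variant))
  for (b in object@blocks)
    cat(sprintf("  %s <- {%s} [%s]\n", b@name,
                paste(b@components, collapse = ", "), b@weightMode))
  if (nrow(object@latents))
    cat(sprintf("  %s =~ %s (reliability %.3g)\n", object@latents$name,
                object@latents$indicator, object@latents$reliability), sep = "")
})

setMethod("show", "ParameterTable", function(object) {
  q <- nFree(object)
  p <- length(object@observed)
  cat(sprintf("ParameterTable ('%s' variant): %d rows, q = %d free, p = %d observed, df = %d\n",
              object@variant, nrow(object@pars), q, p,
              (p * (p + 1)) %/% 2 - q))
  tab <- table(object@pars$role, object@pars$status)
  print(tab)
})

setMethod("show", "SampleMoments", function(object) {
  cat(sprintf("SampleMoments: %d variables, n = %g, divisor '%s'\n",
              ncol(object@S), object@n, object@divisor))
  print(round(object@S, 4))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult ('%s' variant): %s, F = %.6g, logLik = %.4f\n",
              object@table@variant,
              if (object@converged) "converged" else "NOT converged",
              object@discrepancy, object@logLik))
  est <- data.frame(estimate = round(object@estimates, 4),
                    se = round(object@se, 4))
  rownames(est) <- names(object@estimates)
  print(est)
})

setMethod("show", "PopulationModel", function(object) {
  cat(sprintf("PopulationModel ('%s' variant): %d observed variables, %d true parameters\n",
              object@table@variant, length(object@table@observed),
              length(object@theta)))
})
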