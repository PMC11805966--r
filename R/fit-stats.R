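## Global fit assessment: chi-square test, RMSEA/SRMR/CFI/TLI, information
## criteria, and the nested chi-square difference test.  The chi-square
## statistic is n * F with the sample covariance on the divisor-n (ml)
## convention; fitML() enforces that convention, so fit results can be
## used here directly.

#' Chi-square test of exact fit
#'
#' chi2 = n * F-hat with df = p(p+1)/2 - q; the p-value is the upper tail
#' of the chi-square distribution.
#'
#' @param fit a [FitResult-class].
#' @return list with `chisq`, `df`, `pvalue`.
#' @export
chiSquareTest <- function(fit) {
  stopifnot(is(fit, "FitResult"))
  df <- countDegreesOfFreedom(fit@table)
  chisq <- fit@moments@n * fit@discrepancy
  list(chisq = chisq, df = df,
       pvalue = pchisq(chisq, df, lower.tail = FALSE))
}

#' Fit the independence baseline to the moments of a fit
#'
#' All observed variables uncorrelated, variances free; the reference model
#' of the incremental fit indices.
#'
#' @param fit a [FitResult-class] (its ml-scaled moments are reused).
#' @return a [FitResult-class] of the independence model.
#' @export
baselineFit <- function(fit) {
  stopifnot(is(fit, "FitResult"))
  fitML(independenceSpecification(fit@table@observed), fit@moments,
        se = FALSE)
}

#' Global fit indices
#'
#' RMSEA = sqrt(max((chi2 - df) / (df * n), 0)); SRMR is the root mean
#' square of the residuals S - Sigma-hat standardized by the sample
#' standard deviations, over all p(p+1)/2 unique elements including the
#' diagonal; CFI and TLI compare against the independence baseline.
#'
#' @param fit a [FitResult-class].
#' @param baseline independence-model [FitResult-class]; fitted on demand
#'   when `NULL`.
#' @return named numeric vector `rmsea`, `srmr`, `cfi`, `tli` (RMSEA and
#'   TLI are `NA` when df = 0).
#' @export
fitIndices <- function(fit, baseline = NULL) {
  ct <- chiSquareTest(fit)
  n <- fit@moments@n
  if (is.null(baseline)) baseline <- baselineFit(fit)
  cb <- chiSquareTest(baseline)

  ## df = 0: a perfect fit has RMSEA 0 / TLI 1 by convention; a nonzero
  ## chi-square at df = 0 leaves them undefined
  rmsea <- if (ct$df == 0) {
    if (ct$chisq < 1e-8) 0 else NA_real_
  } else sqrt(max((ct$chisq - ct$df) / (ct$df * n), 0))

  S <- fit@moments@S
  sds <- sqrt(diag(S))
  res <- (S - fit@implied) / tcrossprod(sds)
  srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))

  num <- max(ct$chisq - ct$df, 0)
  den <- max(cb$chisq - cb$df, ct$chisq - ct$df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den

  tli <- if (ct$df == 0 || cb$df == 0) {
    if (ct$chisq < 1e-8 && cb$df > 0) 1 else NA_real_
  } else {
    rb <- cb$chisq / cb$df
    (rb - ct$chisq / ct$df) / (rb - 1)
  }
  c(rmsea = rmsea, srmr = srmr, cfi = cfi, tli = tli)
}

#' Information criteria
#'
#' AIC = -2 logL + 2q, BIC = -2 logL + q ln n, and the sample-size-adjusted
#' BIC with penalty ln((n + 2)/24), from the normal-theory log-likelihood.
#'
#' @param fit a [FitResult-class].
#' @return named numeric vector `aic`, `bic`, `sabic`.
#' @export
informationCriteria <- function(fit) {
  stopifnot(is(fit, "FitResult"))
  q <- nFree(fit)
  n <- fit@moments@n
  m2ll <- -2 * fit@logLik
  c(aic = m2ll + 2 * q,
    bic = m2ll + q * log(n),
    sabic = m2ll + q * log((n + 2) / 24))
}

## canonical set of free labels for the structural nesting check
canonicalLabels <- function(table) sort(freeLabels(table))

#' Chi-square difference test for nested models
#'
#' Delta-chi2 = chi2(restricted) - chi2(full) with Delta-df =
#' df(restricted) - df(full), referred to the upper chi-square tail.  Both
#' models must be fitted to identical moments and the restricted model's
#' free-parameter set must nest structurally within the full model's
#' (every restricted free label free in the full table).
#'
#' @param restricted [FitResult-class] of the more constrained model.
#' @param full [FitResult-class] of the less constrained model.
#' @param check verify moments identity and structural nesting (default
#'   TRUE).
#' @return list with `delta.chisq`, `delta.df`, `pvalue`.
#' @export
chiSquareDifference <- function(restricted, full, check = TRUE) {
  stopifnot(is(restricted, "FitResult"), is(full, "FitResult"))
  if (check) {
    o1 <- sort(restricted@table@observed)
    o2 <- sort(full@table@observed)
    if (!identical(o1, o2) ||
        restricted@moments@n != full@moments@n ||
        max(abs(restricted@moments@S[o1, o1] - full@moments@S[o1, o1])) > 1e-10)
      stop("models must be fitted to identical moments")
    if (!all(canonicalLabels(restricted@table) %in%
             canonicalLabels(full@table)))
      stop("models are not nested: restricted free parameters are not a subset of the full model's")
  }
  cr <- chiSquareTest(restricted)
  cf <- chiSquareTest(full)
  d <- cr$chisq - cf$chisq
  ddf <- cr$df - cf$df
  if (ddf < 0) stop("the restricted model must have more degrees of freedom")
  if (d < -1e-6)
    warning("negative chi-square difference: one of the fits likely did not converge")
  d <- max(d, 0)
  pv <- if (ddf == 0) {
    if (d <= 1e-8) 1 else NA_real_
  } else pchisq(d, ddf, lower.tail = FALSE)
  list(delta.chisq = d, delta.df = ddf, pvalue = pv)
}

#' All fit measures of a model
#'
#' @param fit a [FitResult-class].
#' @param baseline optional independence-model fit.
#' @return named numeric vector: `chisq`, `df`, `pvalue`, `rmsea`, `srmr`,
#'   `cfi`, `tli`, `aic`, `bic`, `sabic`, `logl`, `q`, `n`.
#' @export
fitMeasures <- function(fit, baseline = NULL) {
  ct <- chiSquareTest(fit)
  fi <- fitIndices(fit, baseline)
  ic <- informationCriteria(fit)
  c(chisq = ct$chisq, df = ct$df, pvalue = ct$pvalue, fi, ic,
    logl = fit@logLik, q = nFree(fit), n = fit@moments@n)
}

#' Compare fitted models side by side
#'
#' Builds a comparison in the layout customary for composite-specification
#' studies: recovered weights, standardized structural coefficients with
#' standard errors, all fit statistics, and chi-square difference tests for
#' the nested pairs among the supplied fits.
#'
#' @param fits named list of [FitResult-class] objects fitted to the same
#'   moments (models over different variable sets, e.g. a two-step fit,
#'   are allowed; they are skipped by the difference tests).
#' @return an object of class `modelComparison` with elements `weights`,
#'   `paths`, `stats`, `deltas`; printable as an aligned text table.
#' @export
compareModels <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1, !is.null(names(fits)))
  weights <- list()
  paths <- list()
  stats <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (length(f@table@blocks)) {
      bw <- blockWeights(f, se = TRUE)
      bw$model <- nm
      weights[[nm]] <- bw
    }
    std <- standardizedSolution(f, se = TRUE)
    ## structural-level rows only: drop weight regressions (component ->
    ## composite), excrescent covariances and component covariances
    nonStruct <- unlist(lapply(f@table@blocks, function(b)
      c(b$components, b$excrescent)), use.names = FALSE)
    if (!is.null(f@table@meta$latents) && nrow(f@table@meta$latents))
      nonStruct <- c(nonStruct, f@table@meta$latents$indicator)
    keep <- std$status == "free" &
      ((std$role == "path" & !(std$lhs %in% nonStruct)) |
         (std$role == "covariance" & !(std$lhs %in% nonStruct) &
            !(std$rhs %in% nonStruct)))
    if (any(keep)) {
      ps <- std[keep, c("label", "est.std", "se.std")]
      ps$model <- nm
      paths[[nm]] <- ps
    }
    stats[[nm]] <- fitMeasures(f)
  }
  deltas <- list()
  nms <- names(fits)
  if (length(fits) > 1)
    for (i in seq_len(length(fits) - 1))
      for (j in seq(i + 1, length(fits))) {
        d <- tryCatch(chiSquareDifference(fits[[i]], fits[[j]]),
                      error = function(e) NULL)
        rev <- FALSE
        if (is.null(d)) {
          d <- tryCatch(chiSquareDifference(fits[[j]], fits[[i]]),
                        error = function(e) NULL)
          rev <- TRUE
        }
        if (!is.null(d))
          deltas[[paste(nms[i], "vs", nms[j])]] <-
            c(d, list(restricted = if (rev) nms[j] else nms[i],
                      full = if (rev) nms[i] else nms[j]))
      }
  structure(list(weights = if (length(weights)) do.call(rbind, weights),
                 paths = if (length(paths)) do.call(rbind, paths),
                 stats = do.call(cbind, stats),
                 deltas = deltas),
            class = "modelComparison")
}

#' @export
print.modelComparison <- function(x, digits = 3, ...) {
  cat("Model comparison\n================\n")
  if (!is.null(x$weights)) {
    cat("\nRecovered weights (unstandardized, with SE):\n")
    w <- x$weights
    key <- paste0("w_", w$component)
    tab <- tapply(sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
                          w$weight, w$se),
                  list(key, w$model), identity)
    print(tab[unique(key), unique(w$model), drop = FALSE], quote = FALSE)
  }
  if (!is.null(x$paths)) {
    cat("\nStandardized structural coefficients (with SE):\n")
    p <- x$paths
    tab <- tapply(sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
                          p$est.std, p$se.std),
                  list(p$label, p$model), identity)
    print(tab[unique(p$label), unique(p$model), drop = FALSE], quote = FALSE)
  }
  cat("\nFit statistics:\n")
  print(round(x$stats, digits))
  if (length(x$deltas)) {
    cat("\nChi-square difference tests (restricted vs full):\n")
    for (nm in names(x$deltas)) {
      d <- x$deltas[[nm]]
      cat(sprintf("  %s vs %s: delta chi2 = %.*f, delta df = %d, p = %.4g\n",
                  d$restricted, d$full, digits, d$delta.chisq, d$delta.df,
                  d$pvalue))
    }
  }
  invisible(x)
}
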