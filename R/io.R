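## File I/O and the end-to-end analysis driver: covariance/correlation CSV
## input, YAML model configuration, and Table-style comparison reports in
## JSON and aligned text.

#' Read sample moments from CSV
#'
#' Accepts a full square matrix or a lower-triangular matrix (upper cells
#' empty), with variable names in the header; a lower triangle is mirrored.
#' When standard deviations are supplied the matrix is interpreted as a
#' correlation matrix and converted to covariances,
#' S_ij = R_ij * sd_i * sd_j.
#'
#' @param path CSV file with the (co)variance or correlation matrix.
#' @param sds optional named numeric vector, or path to a two-column CSV
#'   (`name`, `sd`), of standard deviations.
#' @param n sample size (required).
#' @param divisor divisor convention of the matrix as stored:
#'   `"unbiased"` (n - 1, the default) or `"ml"` (n).
#' @return a [SampleMoments-class].
#' @export
readMoments <- function(path, sds = NULL, n = NULL,
                        divisor = c("unbiased", "ml")) {
  divisor <- match.arg(divisor)
  if (is.null(n)) stop("the sample size n is required")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.numeric(df[[1]])) {
    rownames(df) <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  M <- as.matrix(df)
  mode(M) <- "numeric"
  nm <- colnames(M)
  if (nrow(M) != ncol(M)) stop("the matrix must be square")
  upper <- upper.tri(M)
  if (anyNA(M[upper])) {
    ## lower-triangular input: mirror the lower triangle
    if (anyNA(M[lower.tri(M, diag = TRUE)]))
      stop("the lower triangle (including the diagonal) must be complete")
    M[upper] <- t(M)[upper]
  } else if (max(abs(M - t(M))) > 1e-8) {
    stop("the matrix is asymmetric beyond 1e-8")
  }
  dimnames(M) <- list(nm, nm)
  if (!is.null(sds)) {
    if (is.character(sds)) {
      sdf <- utils::read.csv(sds, stringsAsFactors = FALSE)
      sds <- setNames(as.numeric(sdf[[2]]), sdf[[1]])
    }
    if (!all(nm %in% names(sds)))
      stop("standard deviations missing for some variables")
    s <- sds[nm]
    M <- M * tcrossprod(s)
  }
  sampleMoments(M, n, divisor = divisor)
}

#' Write sample moments to CSV
#'
#' Values are written as decimal text with 10 significant digits, so a
#' write/read/write round trip is byte-identical.
#'
#' @param moments a [SampleMoments-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeMoments <- function(moments, path) {
  stopifnot(is(moments, "SampleMoments"))
  S <- moments@S
  txt <- matrix(formatC(signif(S, 10), digits = 10, format = "g"),
                nrow(S), dimnames = dimnames(S))
  utils::write.csv(as.data.frame(txt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a model specification from YAML
#'
#' Expected structure: `observed` (optional; inferred from blocks,
#' latents and structural nodes if absent), `blocks` (list with `name`,
#' `components`, optional `weight_mode`, `shared`, `references`), `latents`
#' (list with `name`, `indicator`, `reliability`), `paths` (strings
#' `"A -> B"` or two-element lists), `covariances` (strings `"A ~~ B"` or
#' pairs), `variant`.
#'
#' @param path YAML file.
#' @return a [ModelSpec-class].
#' @export
readModelConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  blocks <- lapply(cfg$blocks, function(b)
    compositeBlock(b$name, unlist(b$components),
                   weightMode = if (!is.null(b$weight_mode)) b$weight_mode
                   else "free",
                   shared = if (!is.null(b$shared)) b$shared
                   else unlist(b$components)[1],
                   references = if (!is.null(b$references))
                     unlist(b$references)
                   else setdiff(unlist(b$components),
                                if (!is.null(b$shared)) b$shared
                                else unlist(b$components)[1])))
  observed <- unlist(cfg$observed)
  if (is.null(observed)) {
    observed <- c(unlist(lapply(blocks, function(b) b@components)),
                  vapply(cfg$latents, function(l) l$indicator, character(1)))
  }
  modelSpec(observed = observed, blocks = blocks, latents = cfg$latents,
            paths = cfg$paths, covariances = cfg$covariances,
            variant = if (!is.null(cfg$variant)) cfg$variant else "free")
}

buildVariantFit <- function(spec, variant, moments, scaling = "effects_coding") {
  moments <- mlScaled(moments)
  if (variant %in% c("free", "unit", "relaxed")) {
    tab <- hoSpecification(spec, variant, sds = moments, scaling = scaling)
    fitML(tab, moments)
  } else if (variant == "one_step") {
    tab <- oneStepSpecification(spec, sds = moments)
    fitML(tab, moments)
  } else if (variant == "two_step") {
    red <- twoStepReduce(moments, spec)
    tab <- twoStepSpecification(spec, sds = red)
    fitML(tab, red)
  } else stop(sprintf("unknown variant '%s'", variant))
}

#' Run a full comparison analysis
#'
#' Loads (or accepts) moments and a model specification, fits the requested
#' variants, and produces a comparison report: recovered weights,
#' standardized structural coefficients with standard errors, all fit
#' statistics, and chi-square difference tests for nested pairs.
#'
#' @param config a list (e.g. parsed from YAML) with entries:
#'   \describe{
#'     \item{model}{a [ModelSpec-class] or path to a YAML model config.}
#'     \item{moments}{a [SampleMoments-class] or path to a moments CSV
#'       (exactly one of `moments`/`data`).}
#'     \item{sds}{optional standard deviations (vector or CSV path) if
#'       `moments` is a correlation matrix.}
#'     \item{n}{sample size (required with a moments file).}
#'     \item{data}{raw data: a data.frame or CSV path; moments are computed
#'       from it.}
#'     \item{divisor}{divisor convention: for a moments file, how it was
#'       computed (default `"unbiased"`); for raw data, how to compute it
#'       (default `"ml"`, matching the chi-square convention).}
#'     \item{variants}{character vector among `"unit"`, `"free"`,
#'       `"relaxed"`, `"one_step"`, `"two_step"`.}
#'     \item{scaling}{scale-fixing method for free-weight composites.}
#'     \item{out}{optional output basename; writes `<out>.json` and
#'       `<out>.txt`.}
#'   }
#' @return a list of class `analysisReport` with `comparison`
#'   (`modelComparison`), `fits` (named list of [FitResult-class]), and
#'   `errors` (named list of messages for variants that failed; partial
#'   results are still returned and written).
#' @export
runAnalysis <- function(config) {
  spec <- config$model
  if (is.character(spec)) spec <- readModelConfig(spec)
  stopifnot(is(spec, "ModelSpec"))
  if (!is.null(config$moments) && !is.null(config$data))
    stop("supply exactly one input source: moments or data")
  if (!is.null(config$moments)) {
    moments <- config$moments
    if (is.character(moments))
      moments <- readMoments(moments, sds = config$sds, n = config$n,
                             divisor = if (!is.null(config$divisor))
                               config$divisor else "unbiased")
  } else if (!is.null(config$data)) {
    dat <- config$data
    if (is.character(dat))
      dat <- utils::read.csv(dat, check.names = FALSE)
    X <- as.matrix(dat[, spec@observed, drop = FALSE])
    n <- nrow(X)
    div <- if (!is.null(config$divisor)) config$divisor else "ml"
    Xc <- sweep(X, 2, colMeans(X))
    S <- crossprod(Xc) / if (div == "ml") n else n - 1
    moments <- sampleMoments(S, n, divisor = div)
  } else stop("supply an input source: moments or data")

  variants <- if (!is.null(config$variants)) config$variants else spec@variant
  scaling <- if (!is.null(config$scaling)) config$scaling else "effects_coding"

  fits <- list()
  errors <- list()
  for (v in variants) {
    res <- tryCatch(buildVariantFit(spec, v, moments, scaling),
                    error = function(e)
                      simpleError(sprintf("[%s] %s", v, conditionMessage(e))))
    if (inherits(res, "error")) errors[[v]] <- conditionMessage(res)
    else fits[[v]] <- res
  }
  if (!length(fits)) stop("all requested variants failed: ",
                          paste(unlist(errors), collapse = "; "))
  comparison <- compareModels(fits)
  report <- structure(list(comparison = comparison, fits = fits,
                           errors = errors), class = "analysisReport")
  if (!is.null(config$out)) writeReport(report, config$out)
  report
}

#' @export
print.analysisReport <- function(x, ...) {
  print(x$comparison, ...)
  if (length(x$errors)) {
    cat("\nVariants that failed:\n")
    for (nm in names(x$errors)) cat(sprintf("  %s: %s\n", nm, x$errors[[nm]]))
  }
  conv <- vapply(x$fits, converged, logical(1))
  if (!all(conv))
    cat("\nWARNING: non-converged fits:", paste(names(conv)[!conv]), "\n")
  invisible(x)
}

#' Write an analysis report to JSON and aligned text
#'
#' @param report an `analysisReport` from [runAnalysis()].
#' @param basename output basename; `<basename>.json` and `<basename>.txt`
#'   are written.
#' @return invisibly, the two paths.
#' @export
writeReport <- function(report, basename) {
  cmp <- report$comparison
  payload <- list(
    fits = lapply(report$fits, function(f) list(
      variant = f@table@variant,
      converged = converged(f),
      estimates = as.list(f@estimates),
      se = as.list(f@se),
      discrepancy = f@discrepancy,
      logLik = f@logLik)),
    weights = cmp$weights,
    standardized_paths = cmp$paths,
    fit_statistics = as.data.frame(cmp$stats),
    delta_chisq = lapply(cmp$deltas, function(d)
      d[c("restricted", "full", "delta.chisq", "delta.df", "pvalue")]),
    errors = report$errors)
  jsonPath <- paste0(basename, ".json")
  txtPath <- paste0(basename, ".txt")
  jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  txt <- utils::capture.output(print(report))
  writeLines(txt, txtPath)
  invisible(c(json = jsonPath, txt = txtPath))
}
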