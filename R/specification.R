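## Builders that turn a declarative ModelSpec into an identified
## ParameterTable: the H-O variants, the one-step and two-step baselines,
## and the independence/saturated reference models.

ptRow <- function(lhs, rhs, role, status, value = NA_real_,
                  expr = NA_character_, start = NA_real_, label = NA_character_) {
  list(lhs = lhs, rhs = rhs, role = role, status = status, value = value,
       expr = expr, start = start, label = label)
}

bindRows <- function(rows) {
  out <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

covLabel <- function(a, b, vars) {
  if (match(a, vars) > match(b, vars)) { tmp <- a; a <- b; b <- tmp }
  list(lhs = a, rhs = b, label = paste0(a, "~~", b))
}

backtick <- function(x) paste0("`", x, "`")

resolveSds <- function(sds) {
  if (is.null(sds)) return(NULL)
  if (is(sds, "SampleMoments")) return(sqrt(diag(sds@S)))
  if (is(sds, "PopulationModel")) return(sqrt(diag(sds@sigma)))
  sds
}

#' Fixed measurement-error variance from an assumed reliability
#'
#' For a single-indicator latent variable with assumed reliability
#' rel(x), the variance of the indicator's random measurement error is
#' fixed to (1 - rel(x)) * var(x).
#'
#' @param reliability assumed reliability, in (0, 1].
#' @param sd standard deviation of the indicator, > 0.
#' @return the fixed error variance (1 - reliability) * sd^2.
#' @examples
#' fixedErrorVariance(0.9, 0.3017)  # 0.009102289
#' @export
fixedErrorVariance <- function(reliability, sd) {
  if (!is.numeric(reliability) || any(reliability <= 0) || any(reliability > 1))
    stop("reliability must lie in (0, 1]")
  if (!is.numeric(sd) || any(sd <= 0))
    stop("sd must be positive")
  (1 - reliability) * sd^2
}

#' Model degrees of freedom
#'
#' df = p(p+1)/2 - q, the number of non-redundant second-order moments
#' minus the number of free parameters (no mean structure is modeled).
#'
#' @param table a [ParameterTable-class].
#' @param p number of observed variables (default: taken from the table).
#' @return nonnegative integer degrees of freedom.
#' @export
countDegreesOfFreedom <- function(table, p = length(table@observed)) {
  q <- nFree(table)
  df <- as.integer((p * (p + 1)) %/% 2 - q)
  if (df < 0L)
    stop(sprintf("over-parameterized model: q = %d exceeds %d moments",
                 q, (p * (p + 1)) %/% 2))
  df
}

## structural rows shared by the H-O and one-step builders: latents,
## passthrough observed variables, paths, declared covariances.
structuralRows <- function(spec, sds, vars, skipCov = character()) {
  rows <- list()
  if (nrow(spec@latents)) {
    if (is.null(sds))
      stop("sds (or moments) needed to fix latent error variances")
    for (i in seq_len(nrow(spec@latents))) {
      L <- spec@latents$name[i]; ind <- spec@latents$indicator[i]
      rel <- spec@latents$reliability[i]
      if (!(ind %in% names(sds)))
        stop(sprintf("no sd supplied for indicator '%s'", ind))
      rows <- c(rows, list(
        ptRow(L, ind, "loading", "fixed", value = 1,
              label = paste0(L, "=~", ind)),
        ptRow(ind, ind, "variance", "fixed",
              value = fixedErrorVariance(rel, sds[[ind]]),
              label = paste0(ind, "~~", ind)),
        ptRow(L, L, "variance", "free", start = NA_real_,
              label = paste0(L, "~~", L))))
    }
  }
  comps <- specComponents(spec)
  inds <- if (nrow(spec@latents)) spec@latents$indicator else character()
  passthrough <- setdiff(spec@observed, c(comps, inds))
  for (v in passthrough)
    rows <- c(rows, list(ptRow(v, v, "variance", "free", start = NA_real_,
                               label = paste0(v, "~~", v))))
  if (nrow(spec@paths))
    for (i in seq_len(nrow(spec@paths))) {
      from <- spec@paths$from[i]; to <- spec@paths$to[i]
      rows <- c(rows, list(ptRow(from, to, "path", "free", start = 0,
                                 label = paste0(to, "~", from))))
    }
  if (nrow(spec@covariances))
    for (i in seq_len(nrow(spec@covariances))) {
      cl <- covLabel(spec@covariances$var1[i], spec@covariances$var2[i], vars)
      if (cl$label %in% skipCov) next
      rows <- c(rows, list(ptRow(cl$lhs, cl$rhs, "covariance", "free",
                                 start = 0, label = cl$label)))
    }
  rows
}

blockMeta <- function(b) {
  list(name = b@name, components = b@components,
       excrescent = excrescentNames(b), mode = b@weightMode,
       shared = b@shared, references = b@references)
}

#' Build an identified H-O parameter table
#'
#' Constructs the constrained parameterization of the Henseler-Ogasawara
#' specification for a declarative model.  Per composite block of k
#' components, the composite of interest plus k - 1 excrescent variables
#' are introduced; identification follows the refined rules: the scale of
#' the composite of interest is fixed (by default, effects coding: its
#' loadings sum to 1); each excrescent variable carries exactly two
#' loadings, its reference component fixed at 1 and the block's shared
#' component either fixed at -1 (unit weights) or freely estimated (free
#' weights); covariances between the composite of interest and its own
#' excrescent variables are fixed to 0; component error variances are fixed
#' to 0.  The relaxed variant additionally frees all covariances between
#' each block's excrescent variables and the other blocks' composites and
#' excrescent variables, so that cross-block component covariances are no
#' longer fully carried by the composites.
#'
#' @param spec a [ModelSpec-class].
#' @param variant `"free"`, `"unit"`, or `"relaxed"`.
#' @param sds named numeric vector of observed standard deviations (or a
#'   [SampleMoments-class]/[PopulationModel-class] to take them from); used
#'   for fixed latent error variances.
#' @param scaling scale-fixing method for free-weight composites:
#'   `"effects_coding"` (sum of composite loadings = 1, the default),
#'   `"reference"` (first composite loading fixed to 1) or
#'   `"variance_standardization"` (composite variance fixed to 1).  Unit
#'   weight composites always use effects coding.
#' @return a [ParameterTable-class].
#' @export
hoSpecification <- function(spec, variant = spec@variant, sds = NULL,
                            scaling = c("effects_coding", "reference",
                                        "variance_standardization")) {
  stopifnot(is(spec, "ModelSpec"))
  validObject(spec)
  variant <- match.arg(variant, c("free", "unit", "relaxed"))
  scaling <- match.arg(scaling)
  sds <- resolveSds(sds)

  constructs <- unlist(lapply(spec@blocks, function(b)
    c(b@name, excrescentNames(b))), use.names = FALSE)
  vars <- c(spec@observed, constructs,
            if (nrow(spec@latents)) spec@latents$name else character())
  rows <- list()

  for (b in spec@blocks) {
    mode <- if (variant == "unit") "unit" else b@weightMode
    scal <- if (mode == "unit") "effects_coding" else scaling
    C <- b@name; comps <- b@components; k <- length(comps)
    nus <- excrescentNames(b)

    if (mode == "free" && variant %in% c("free", "relaxed")) {
      neighbors <- c(spec@paths$from, spec@paths$to,
                     spec@covariances$var1, spec@covariances$var2)
      if (!(C %in% neighbors))
        stop(sprintf(paste("identification error: free-weight composite '%s'",
                           "must be connected to at least one other variable",
                           "of the model"), C))
    }

    ## composite-of-interest loadings under the chosen scale fixing
    lab <- paste0(C, "=~", comps)
    if (scal == "effects_coding") {
      for (i in seq_len(k - 1L))
        rows <- c(rows, list(ptRow(C, comps[i], "loading", "free",
                                   start = 0, label = lab[i])))
      expr <- paste("1", paste("-", backtick(lab[seq_len(k - 1L)]),
                               collapse = " "))
      rows <- c(rows, list(ptRow(C, comps[k], "loading", "constrained",
                                 expr = expr, label = lab[k])))
    } else if (scal == "reference") {
      rows <- c(rows, list(ptRow(C, comps[1], "loading", "fixed", value = 1,
                                 label = lab[1])))
      for (i in seq_len(k)[-1])
        rows <- c(rows, list(ptRow(C, comps[i], "loading", "free",
                                   start = 0, label = lab[i])))
    } else {  # variance standardization: all loadings free, var(C) = 1
      for (i in seq_len(k))
        rows <- c(rows, list(ptRow(C, comps[i], "loading", "free",
                                   start = 1 / k, label = lab[i])))
    }

    ## excrescent loadings: reference fixed at 1; shared fixed at -1 (unit)
    ## or free (free/relaxed); all other loadings implicitly 0
    for (j in seq_len(k - 1L)) {
      nu <- nus[j]; ref <- b@references[j]
      rows <- c(rows, list(ptRow(nu, ref, "loading", "fixed", value = 1,
                                 label = paste0(nu, "=~", ref))))
      sl <- paste0(nu, "=~", b@shared)
      if (mode == "unit")
        rows <- c(rows, list(ptRow(nu, b@shared, "loading", "fixed",
                                   value = -1, label = sl)))
      else
        rows <- c(rows, list(ptRow(nu, b@shared, "loading", "free",
                                   start = -1, label = sl)))
    }

    ## construct variances; composite fixed at 1 under variance scaling
    if (scal == "variance_standardization")
      rows <- c(rows, list(ptRow(C, C, "variance", "fixed", value = 1,
                                 label = paste0(C, "~~", C))))
    else
      rows <- c(rows, list(ptRow(C, C, "variance", "free", start = NA_real_,
                                 label = paste0(C, "~~", C))))
    for (nu in nus)
      rows <- c(rows, list(ptRow(nu, nu, "variance", "free", start = NA_real_,
                                 label = paste0(nu, "~~", nu))))

    ## within-block excrescent covariances are free
    if (k > 2L)
      for (i in seq_len(k - 2L))
        for (j in seq(i + 1L, k - 1L)) {
          cl <- covLabel(nus[i], nus[j], vars)
          rows <- c(rows, list(ptRow(cl$lhs, cl$rhs, "covariance", "free",
                                     start = 0, label = cl$label)))
        }

    ## Rule 4: composite of interest uncorrelated with own excrescent vars
    for (nu in nus) {
      cl <- covLabel(C, nu, vars)
      rows <- c(rows, list(ptRow(cl$lhs, cl$rhs, "covariance", "fixed",
                                 value = 0, label = cl$label)))
    }

    ## components carry no measurement error
    for (x in comps)
      rows <- c(rows, list(ptRow(x, x, "variance", "fixed", value = 0,
                                 label = paste0(x, "~~", x))))
  }

  ## relaxed variant: free covariances between each block's excrescent
  ## variables and every other block's composite and excrescent variables
  if (variant == "relaxed" && length(spec@blocks) > 1L) {
    nb <- length(spec@blocks)
    for (i in seq_len(nb - 1L))
      for (j in seq(i + 1L, nb)) {
        bi <- spec@blocks[[i]]; bj <- spec@blocks[[j]]
        nusI <- excrescentNames(bi); nusJ <- excrescentNames(bj)
        pairs <- rbind(expand.grid(a = nusI, b = bj@name,
                                   stringsAsFactors = FALSE),
                       expand.grid(a = nusJ, b = bi@name,
                                   stringsAsFactors = FALSE),
                       expand.grid(a = nusI, b = nusJ,
                                   stringsAsFactors = FALSE))
        for (r in seq_len(nrow(pairs))) {
          cl <- covLabel(pairs$a[r], pairs$b[r], vars)
          rows <- c(rows, list(ptRow(cl$lhs, cl$rhs, "covariance", "free",
                                     start = 0, label = cl$label)))
        }
      }
  }

  rows <- c(rows, structuralRows(spec, sds, vars))
  new("ParameterTable", pars = bindRows(rows), variables = vars,
      observed = spec@observed, blocks = lapply(spec@blocks, blockMeta),
      variant = variant,
      meta = list(scaling = scaling, sds = sds, latents = spec@latents))
}

#' Build a one-step parameter table
#'
#' The one-step (composite-as-dependent-latent) baseline: each composite is
#' an endogenous variable regressed on its components with its disturbance
#' variance fixed to 0 and one component's weight fixed to 1 to set the
#' scale; all variances and covariances among the components -- within and
#' across blocks -- are free.  Because every composite is a dependent
#' variable, no covariance involving a composite can be specified.
#'
#' @param spec a [ModelSpec-class].
#' @param sds named numeric vector of observed standard deviations (or an
#'   object to take them from), for fixed latent error variances.
#' @param fixWeights optional named character vector mapping block names to
#'   the component whose weight is fixed at 1; default is each block's last
#'   component.  An `NA` entry leaves all of that block's weights free,
#'   which is rejected as unidentified (the composite has no scale).
#' @return a [ParameterTable-class].
#' @export
oneStepSpecification <- function(spec, sds = NULL, fixWeights = NULL) {
  stopifnot(is(spec, "ModelSpec"))
  validObject(spec)
  sds <- resolveSds(sds)
  blockNames <- vapply(spec@blocks, function(b) b@name, character(1))

  if (nrow(spec@covariances)) {
    touches <- spec@covariances$var1 %in% blockNames |
      spec@covariances$var2 %in% blockNames
    if (any(touches))
      stop(paste("in the one-step approach composites are dependent",
                 "variables: it is not possible to specify a covariance",
                 "involving a composite"))
  }
  if (nrow(spec@paths) && any(spec@paths$to %in% blockNames))
    stop(paste("the one-step approach cannot model effects on a composite;",
               "only its components may point at it"))

  vars <- c(spec@observed, blockNames,
            if (nrow(spec@latents)) spec@latents$name else character())
  rows <- list()
  comps <- specComponents(spec)

  ## exogenous components: all variances and pairwise covariances free
  for (x in comps)
    rows <- c(rows, list(ptRow(x, x, "variance", "free", start = NA_real_,
                               label = paste0(x, "~~", x))))
  if (length(comps) > 1L)
    for (i in seq_len(length(comps) - 1L))
      for (j in seq(i + 1L, length(comps))) {
        cl <- covLabel(comps[i], comps[j], vars)
        rows <- c(rows, list(ptRow(cl$lhs, cl$rhs, "covariance", "free",
                                   start = NA_real_, label = cl$label)))
      }

  ## composites regressed on their components, disturbance fixed to 0
  for (b in spec@blocks) {
    C <- b@name
    fixed <- if (!is.null(fixWeights) && C %in% names(fixWeights))
      fixWeights[[C]] else b@components[length(b@components)]
    if (is.na(fixed))
      stop(sprintf(paste("identification error: composite '%s' has no fixed",
                         "weight, so its scale is indeterminate"), C))
    if (!(fixed %in% b@components))
      stop(sprintf("'%s' is not a component of block '%s'", fixed, C))
    for (x in b@components) {
      labw <- paste0(C, "~", x)
      if (x == fixed)
        rows <- c(rows, list(ptRow(x, C, "path", "fixed", value = 1,
                                   label = labw)))
      else
        rows <- c(rows, list(ptRow(x, C, "path", "free", start = 1,
                                   label = labw)))
    }
    rows <- c(rows, list(ptRow(C, C, "variance", "fixed", value = 0,
                               label = paste0(C, "~~", C))))
  }

  rows <- c(rows, structuralRows(spec, sds, vars))
  new("ParameterTable", pars = bindRows(rows), variables = vars,
      observed = spec@observed, blocks = lapply(spec@blocks, blockMeta),
      variant = "one_step",
      meta = list(scaling = "reference", sds = sds, latents = spec@latents))
}

#' Build the structural table of the two-step baseline
#'
#' In the two-step approach composite scores are computed before the
#' analysis ([twoStepReduce()]); the structural model is then fitted to the
#' reduced moments with each composite entering as an observed exogenous
#' variable.  This builder returns that structural-only parameter table;
#' the composite score variables carry free variances and the declared
#' covariances.
#'
#' @param spec a [ModelSpec-class] (the full model; blocks are collapsed to
#'   observed score variables).
#' @param sds named numeric vector of standard deviations on the reduced
#'   variable set (or an object to take them from).
#' @return a [ParameterTable-class] over the reduced variables.
#' @export
twoStepSpecification <- function(spec, sds = NULL) {
  stopifnot(is(spec, "ModelSpec"))
  validObject(spec)
  blockNames <- vapply(spec@blocks, function(b) b@name, character(1))
  comps <- specComponents(spec)
  reducedObs <- c(blockNames, setdiff(spec@observed, comps))
  rspec <- modelSpec(observed = reducedObs, blocks = list(),
                     latents = spec@latents, paths = spec@paths,
                     covariances = spec@covariances, variant = "two_step")
  tab <- hoSpecification(rspec, variant = "free", sds = resolveSds(sds))
  tab@variant <- "two_step"
  tab
}

#' Independence (baseline) parameter table
#'
#' All observed variables uncorrelated with free variances; the null model
#' used by incremental fit indices (CFI, TLI).
#'
#' @param names observed variable names.
#' @return a [ParameterTable-class] with q = p free parameters.
#' @export
independenceSpecification <- function(names) {
  rows <- lapply(names, function(v)
    ptRow(v, v, "variance", "free", start = NA_real_,
          label = paste0(v, "~~", v)))
  new("ParameterTable", pars = bindRows(rows), variables = names,
      observed = names, blocks = list(), variant = "independence",
      meta = list())
}

#' Saturated parameter table
#'
#' All variances and covariances of the observed variables free; fits any
#' admissible covariance matrix exactly (df = 0).
#'
#' @param names observed variable names.
#' @return a [ParameterTable-class] with q = p(p+1)/2 free parameters.
#' @export
saturatedSpecification <- function(names) {
  rows <- lapply(names, function(v)
    ptRow(v, v, "variance", "free", start = NA_real_,
          label = paste0(v, "~~", v)))
  p <- length(names)
  if (p > 1L)
    for (i in seq_len(p - 1L))
      for (j in seq(i + 1L, p))
        rows <- c(rows, list(ptRow(names[i], names[j], "covariance", "free",
                                   start = NA_real_,
                                   label = paste0(names[i], "~~", names[j]))))
  new("ParameterTable", pars = bindRows(rows), variables = names,
      observed = names, blocks = list(), variant = "saturated",
      meta = list())
}

#' Serialize a parameter table to CSV
#'
#' @param table a [ParameterTable-class].
#' @param path output file path.
#' @return invisibly, the data.frame written.
#' @export
writeParameterTable <- function(table, path) {
  df <- table@pars
  df$value_or_expression <- ifelse(df$status == "constrained", df$expr,
                                   ifelse(df$status == "fixed",
                                          as.character(df$value), ""))
  out <- df[, c("lhs", "rhs", "role", "status", "value_or_expression", "label")]
  names(out)[1:2] <- c("source", "target")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(out)
}

#' Read a parameter table from CSV
#'
#' Inverse of [writeParameterTable()].  Block metadata and data-dependent
#' starting values are not stored in the CSV, so the result is a generic
#' table: it can be resolved and fitted, but [recoverWeights()] needs the
#' original builder output.
#'
#' @param path CSV with columns `source`, `target`, `role`, `status`,
#'   `value_or_expression`, `label`.
#' @param observed observed variable names, in moment-matrix order.
#' @param variables all model variable names; defaults to `observed`
#'   followed by the remaining names in order of first appearance.
#' @param variant variant tag to store on the table.
#' @return a [ParameterTable-class].
#' @export
readParameterTable <- function(path, observed, variables = NULL,
                               variant = "custom") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  value <- rep(NA_real_, nrow(df))
  fixed <- df$status == "fixed"
  value[fixed] <- as.numeric(df$value_or_expression[fixed])
  expr <- ifelse(df$status == "constrained", df$value_or_expression,
                 NA_character_)
  pars <- data.frame(lhs = df$source, rhs = df$target, role = df$role,
                     status = df$status, value = value, expr = expr,
                     start = NA_real_, label = df$label)
  if (is.null(variables))
    variables <- c(observed,
                   setdiff(unique(c(pars$lhs, pars$rhs)), observed))
  new("ParameterTable", pars = pars, variables = variables,
      observed = observed, blocks = list(), variant = variant,
      meta = list())
}
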