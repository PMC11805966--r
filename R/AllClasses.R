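#' @import methods
#' @importFrom stats pchisq setNames rnorm runif optim nlminb cov
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Composite block
#'
#' Describes one composite of interest and the components it is built from.
#' In the Henseler-Ogasawara (H-O) specification a block of k components
#' yields, next to the composite of interest, k - 1 auxiliary "excrescent"
#' variables that span the remainder of the components' space.  Each
#' excrescent variable touches exactly two components: the block's shared
#' component and one reference component; no component serves as reference
#' twice.
#'
#' @slot name construct name of the composite of interest.
#' @slot components ordered character vector of k >= 2 observed components.
#' @slot weightMode `"free"` (weights estimated) or `"unit"` (sum of the
#'   components).
#' @slot shared the component whose excrescent loadings are freed in the
#'   free-weight variant; defaults to the first component.
#' @slot references ordered assignment of the remaining k - 1 components,
#'   one per excrescent variable.
#' @export
setClass("CompositeBlock",
  representation(
    name = "character",
    components = "character",
    weightMode = "character",
    shared = "character",
    references = "character"
  )
)

setValidity("CompositeBlock", function(object) {
  msgs <- character()
  k <- length(object@components)
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "block needs a single non-empty name")
  if (k < 2L)
    msgs <- c(msgs, "a composite block needs at least 2 components")
  if (anyDuplicated(object@components))
    msgs <- c(msgs, "components must be distinct")
  if (!(object@weightMode %in% c("free", "unit")))
    msgs <- c(msgs, "weightMode must be 'free' or 'unit'")
  if (length(object@shared) != 1L || !(object@shared %in% object@components))
    msgs <- c(msgs, "shared component must be one of the components")
  if (length(object@references) != k - 1L)
    msgs <- c(msgs, sprintf("need exactly %d reference components", k - 1L))
  if (object@shared %in% object@references)
    msgs <- c(msgs, "the shared component cannot also be a reference")
  if (anyDuplicated(object@references))
    msgs <- c(msgs, "no component may serve as reference twice")
  if (!all(object@references %in% object@components))
    msgs <- c(msgs, "references must be components of the block")
  if (length(msgs)) msgs else TRUE
})

#' Create a composite block
#'
#' @param name construct name.
#' @param components ordered character vector of observed component names.
#' @param weightMode `"free"` or `"unit"`.
#' @param shared component whose excrescent loadings are freed in the
#'   free-weight variant (default: first component).
#' @param references ordered references, one per excrescent variable
#'   (default: the non-shared components in declared order).
#' @return a [CompositeBlock-class] object.
#' @examples
#' compositeBlock("Soil", c("text", "mois", "pH"))
#' @export
compositeBlock <- function(name, components, weightMode = "free",
                           shared = components[1L],
                           references = setdiff(components, shared)) {
  new("CompositeBlock", name = name, components = components,
      weightMode = weightMode, shared = shared, references = references)
}

excrescentNames <- function(block) {
  k <- length(block@components)
  paste0("nu", seq_len(k - 1L), "_", block@name)
}

#' Declarative model description
#'
#' Holds the observed variables, composite blocks, single-indicator latent
#' variables with assumed reliabilities, directed structural paths, and
#' exogenous covariances of a composite structural equation model, plus a
#' default specification variant.
#'
#' @slot observed ordered character vector of observed variable names.
#' @slot blocks list of [CompositeBlock-class] objects.
#' @slot latents data.frame with columns `name`, `indicator`, `reliability`.
#' @slot paths data.frame with columns `from`, `to`.
#' @slot covariances data.frame with columns `var1`, `var2`.
#' @slot variant one of `"free"`, `"unit"`, `"relaxed"`, `"one_step"`,
#'   `"two_step"`.
#' @export
setClass("ModelSpec",
  representation(
    observed = "character",
    blocks = "list",
    latents = "data.frame",
    paths = "data.frame",
    covariances = "data.frame",
    variant = "character"
  )
)

specConstructs <- function(spec) {
  c(vapply(spec@blocks, function(b) b@name, character(1)),
    if (nrow(spec@latents)) spec@latents$name else character())
}

specComponents <- function(spec) {
  unlist(lapply(spec@blocks, function(b) b@components), use.names = FALSE)
}

## structural nodes usable as path/covariance endpoints
specNodes <- function(spec) {
  comps <- specComponents(spec)
  inds <- if (nrow(spec@latents)) spec@latents$indicator else character()
  c(specConstructs(spec), setdiff(spec@observed, c(comps, inds)))
}

setValidity("ModelSpec", function(object) {
  msgs <- character()
  comps <- specComponents(object)
  if (anyDuplicated(comps))
    msgs <- c(msgs, "component names must be disjoint across blocks")
  inds <- if (nrow(object@latents)) object@latents$indicator else character()
  if (length(intersect(comps, inds)))
    msgs <- c(msgs, "components and latent indicators must be disjoint")
  if (!all(c(comps, inds) %in% object@observed))
    msgs <- c(msgs, "components and indicators must be observed variables")
  cons <- specConstructs(object)
  if (anyDuplicated(cons))
    msgs <- c(msgs, "construct names must be unique")
  if (length(intersect(cons, object@observed)))
    msgs <- c(msgs, "construct names must not collide with observed names")
  if (nrow(object@latents) &&
      any(object@latents$reliability <= 0 | object@latents$reliability > 1))
    msgs <- c(msgs, "latent reliabilities must lie in (0, 1]")
  nodes <- specNodes(object)
  if (nrow(object@paths)) {
    ends <- unique(c(object@paths$from, object@paths$to))
    if (!all(ends %in% nodes))
      msgs <- c(msgs, "path endpoints must be declared constructs or free observed variables")
    if (hasCycle(object@paths))
      msgs <- c(msgs, "the structural graph must be acyclic")
  }
  if (nrow(object@covariances)) {
    ends <- unique(c(object@covariances$var1, object@covariances$var2))
    if (!all(ends %in% nodes))
      msgs <- c(msgs, "covariance endpoints must be declared constructs or free observed variables")
  }
  if (!(object@variant %in% c("free", "unit", "relaxed", "one_step", "two_step")))
    msgs <- c(msgs, "unknown variant")
  if (length(msgs)) msgs else TRUE
})

## simple DFS cycle check on a from/to edge list
hasCycle <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  state <- setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 active, 2 done
  adj <- split(edges$to, factor(edges$from, levels = nodes))
  visit <- function(v) {
    if (state[[v]] == 1L) return(TRUE)
    if (state[[v]] == 2L) return(FALSE)
    state[[v]] <<- 1L
    for (w in adj[[v]]) if (visit(w)) return(TRUE)
    state[[v]] <<- 2L
    FALSE
  }
  for (v in nodes) if (visit(v)) return(TRUE)
  FALSE
}

edgeFrame <- function(x, cols) {
  if (is.null(x)) {
    out <- as.data.frame(setNames(rep(list(character()), length(cols)), cols))
    return(out)
  }
  if (is.data.frame(x)) {
    names(x)[seq_along(cols)] <- cols
    return(x[, cols, drop = FALSE])
  }
  ## list of 2-element vectors or "A -> B"/"A ~~ B" strings
  rows <- lapply(x, function(e) {
    if (is.character(e) && length(e) == 1L)
      e <- strsplit(e, "\\s*(->|~~)\\s*")[[1]]
    if (length(e) != 2L) stop("each edge needs exactly two endpoints")
    as.character(e)
  })
  out <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  names(out) <- cols
  out
}

#' Create a model specification
#'
#' @param observed ordered character vector of observed variable names.
#' @param blocks list of [compositeBlock()] objects.
#' @param latents `NULL`, or a data.frame / list with elements `name`,
#'   `indicator`, `reliability` describing single-indicator latent variables.
#' @param paths directed structural paths: a two-column data.frame
#'   (`from`, `to`), a list of pairs, or strings `"A -> B"`.
#' @param covariances exogenous covariances: two-column data.frame, list of
#'   pairs, or strings `"A ~~ B"`.
#' @param variant default specification variant, one of `"free"`, `"unit"`,
#'   `"relaxed"`, `"one_step"`, `"two_step"`.
#' @return a [ModelSpec-class] object.
#' @export
modelSpec <- function(observed, blocks = list(), latents = NULL,
                      paths = NULL, covariances = NULL, variant = "free") {
  if (is.list(latents) && !is.data.frame(latents) && length(latents))
    latents <- do.call(rbind.data.frame,
                       lapply(latents, function(l)
                         data.frame(name = l$name, indicator = l$indicator,
                                    reliability = as.numeric(l$reliability))))
  if (is.null(latents) || !length(latents))
    latents <- data.frame(name = character(), indicator = character(),
                          reliability = numeric())
  new("ModelSpec", observed = observed, blocks = blocks, latents = latents,
      paths = edgeFrame(paths, c("from", "to")),
      covariances = edgeFrame(covariances, c("var1", "var2")),
      variant = variant)
}

#' Constrained parameter table
#'
#' The identified parameterization of a model: one row per model matrix
#' entry that is free, fixed, or affine-constrained in terms of free
#' parameters.  Together with values for the free labels, the table
#' determines the full coefficient matrix B and exogenous covariance matrix
#' Psi of the all-endogenous (RAM-style) representation, and hence the
#' model-implied covariance matrix of the observed variables.
#'
#' @slot pars data.frame with columns `lhs`, `rhs`, `role` (one of
#'   `"loading"`, `"path"`, `"variance"`, `"covariance"`), `status`
#'   (`"free"`, `"fixed"`, `"constrained"`), `value` (fixed value), `expr`
#'   (affine expression over free labels, for constrained rows), `start`
#'   (starting value; `NA` means data-dependent default), `label`.
#' @slot variables all model variables, observed first.
#' @slot observed observed variable names (the order of the implied matrix).
#' @slot blocks list of per-block metadata (`name`, `components`,
#'   `excrescent`, `mode`, `shared`, `references`).
#' @slot variant the specification variant the table encodes.
#' @slot meta list of auxiliary information (scaling method, sds used for
#'   fixed error variances, ...).
#' @export
setClass("ParameterTable",
  representation(
    pars = "data.frame",
    variables = "character",
    observed = "character",
    blocks = "list",
    variant = "character",
    meta = "list"
  )
)

setValidity("ParameterTable", function(object) {
  msgs <- character()
  p <- object@pars
  need <- c("lhs", "rhs", "role", "status", "value", "expr", "start", "label")
  if (!all(need %in% names(p)))
    return(paste("pars must have columns:", paste(need, collapse = ", ")))
  if (!all(p$role %in% c("loading", "path", "variance", "covariance")))
    msgs <- c(msgs, "unknown role in parameter table")
  if (!all(p$status %in% c("free", "fixed", "constrained")))
    msgs <- c(msgs, "unknown status in parameter table")
  if (!all(c(p$lhs, p$rhs) %in% object@variables))
    msgs <- c(msgs, "all row endpoints must be model variables")
  if (!all(object@observed %in% object@variables))
    msgs <- c(msgs, "observed names must be model variables")
  vr <- p$role == "variance"
  if (any(p$lhs[vr] != p$rhs[vr]))
    msgs <- c(msgs, "variance rows must have lhs == rhs")
  free <- p$status == "free"
  if (anyDuplicated(p$label[free]))
    msgs <- c(msgs, "free labels must be unique")
  con <- which(p$status == "constrained")
  if (length(con)) {
    lab <- p$label[free]
    for (i in con) {
      vars <- all.vars(parse(text = p$expr[i])[[1]])
      if (!all(vars %in% lab))
        msgs <- c(msgs, sprintf(
          "constrained row %s references non-free label(s): %s",
          p$label[i], paste(setdiff(vars, lab), collapse = ", ")))
    }
  }
  key <- paste(p$lhs, p$rhs, p$role)
  if (anyDuplicated(key))
    msgs <- c(msgs, "duplicate parameter rows")
  if (length(msgs)) msgs else TRUE
})

#' Sample moments
#'
#' A sample covariance matrix with its sample size and divisor convention.
#'
#' @slot S symmetric covariance matrix with dimnames.
#' @slot n sample size.
#' @slot divisor `"ml"` (divisor n) or `"unbiased"` (divisor n - 1).
#' @export
setClass("SampleMoments",
  representation(S = "matrix", n = "numeric", divisor = "character")
)

setValidity("SampleMoments", function(object) {
  msgs <- character()
  S <- object@S
  if (is.null(colnames(S)) || is.null(rownames(S)) ||
      !identical(colnames(S), rownames(S)))
    msgs <- c(msgs, "S needs identical row and column names")
  if (nrow(S) != ncol(S)) msgs <- c(msgs, "S must be square")
  else if (max(abs(S - t(S))) > 1e-8)
    msgs <- c(msgs, "S must be symmetric (within 1e-8)")
  if (length(object@n) != 1L || object@n < 1)
    msgs <- c(msgs, "n must be a single positive number")
  if (!(object@divisor %in% c("ml", "unbiased")))
    msgs <- c(msgs, "divisor must be 'ml' or 'unbiased'")
  if (length(msgs)) msgs else TRUE
})

#' Create sample moments
#'
#' @param S symmetric covariance matrix (named).
#' @param n sample size.
#' @param divisor `"ml"` (divisor n) or `"unbiased"` (divisor n - 1).
#' @param names optional variable names overriding `dimnames(S)`.
#' @return a [SampleMoments-class] object.
#' @export
sampleMoments <- function(S, n, divisor = c("unbiased", "ml"), names = NULL) {
  divisor <- match.arg(divisor)
  S <- as.matrix(S)
  if (!is.null(names)) dimnames(S) <- list(names, names)
  S <- (S + t(S)) / 2
  new("SampleMoments", S = S, n = as.numeric(n), divisor = divisor)
}

#' Rescale moments to the maximum-likelihood divisor
#'
#' Converts an unbiased (divisor n - 1) covariance matrix to the divisor-n
#' convention used by the normal-theory discrepancy and the chi-square
#' statistic.  Moments already on the ml convention pass through unchanged.
#'
#' @param moments a [SampleMoments-class] object.
#' @return a [SampleMoments-class] object with `divisor = "ml"`.
#' @export
mlScaled <- function(moments) {
  stopifnot(is(moments, "SampleMoments"))
  if (moments@divisor == "ml") return(moments)
  sampleMoments(moments@S * (moments@n - 1) / moments@n, moments@n,
                divisor = "ml")
}

#' Maximum-likelihood fit result
#'
#' @slot estimates named numeric vector of free-parameter estimates.
#' @slot se named numeric vector of standard errors (expected information).
#' @slot vcovTheta estimated covariance matrix of the free parameters.
#' @slot implied model-implied covariance matrix of the observed variables.
#' @slot discrepancy minimized ML discrepancy value.
#' @slot logLik normal-theory log-likelihood at the optimum.
#' @slot converged logical convergence flag.
#' @slot iterations iteration count of the optimizer.
#' @slot gradNorm max-norm of the discrepancy gradient at the solution.
#' @slot table the fitted [ParameterTable-class].
#' @slot moments the [SampleMoments-class] actually fitted (ml divisor).
#' @export
setClass("FitResult",
  representation(
    estimates = "numeric",
    se = "numeric",
    vcovTheta = "matrix",
    implied = "matrix",
    discrepancy = "numeric",
    logLik = "numeric",
    converged = "logical",
    iterations = "numeric",
    gradNorm = "numeric",
    table = "ParameterTable",
    moments = "SampleMoments"
  )
)

#' Population model
#'
#' A parameter table together with true values for all of its free labels
#' and the implied population covariance matrix; the sampling unit of the
#' synthetic-data generator.
#'
#' @slot table a [ParameterTable-class].
#' @slot theta named true values for all free labels.
#' @slot sigma implied population covariance of the observed variables.
#' @slot spec the generating [ModelSpec-class].
#' @export
setClass("PopulationModel",
  representation(
    table = "ParameterTable",
    theta = "numeric",
    sigma = "matrix",
    spec = "ModelSpec"
  )
)

setValidity("PopulationModel", function(object) {
  msgs <- character()
  free <- object@table@pars$label[object@table@pars$status == "free"]
  if (!identical(names(object@theta), free))
    msgs <- c(msgs, "theta names must equal the table's free labels, in order")
  ev <- eigen(object@sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    msgs <- c(msgs, "population covariance must be positive definite")
  if (length(msgs)) msgs else TRUE
})
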