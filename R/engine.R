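## All-endogenous (RAM-style) covariance engine: a ParameterTable plus free
## parameter values determine a coefficient matrix B over all model
## variables (observed, composites, excrescent variables, latents) and an
## exogenous/residual covariance matrix Psi; the implied covariance of the
## observed variables is G (I-B)^-1 Psi (I-B)^-T G'.

## Compile a ParameterTable into index vectors and constant affine maps so
## that repeated evaluation inside the optimizer is cheap.
compileTable <- function(table) {
  validObject(table)
  pars <- table@pars
  vars <- table@variables
  m <- length(vars)
  obsIdx <- match(table@observed, vars)
  li <- match(pars$lhs, vars)
  ri <- match(pars$rhs, vars)
  isB <- pars$role %in% c("loading", "path")
  ## B[target, source]: loadings run construct -> component (lhs -> rhs),
  ## paths run from -> to (lhs -> rhs)
  bIdx <- ri + (li - 1L) * m
  pIdx1 <- li + (ri - 1L) * m
  pIdx2 <- ri + (li - 1L) * m

  B0 <- matrix(0, m, m, dimnames = list(vars, vars))
  P0 <- matrix(0, m, m, dimnames = list(vars, vars))
  fx <- which(pars$status == "fixed")
  for (i in fx) {
    if (isB[i]) B0[bIdx[i]] <- pars$value[i]
    else { P0[pIdx1[i]] <- pars$value[i]; P0[pIdx2[i]] <- pars$value[i] }
  }

  free <- which(pars$status == "free")
  q <- length(free)
  labels <- pars$label[free]
  con <- which(pars$status == "constrained")

  ## affine maps for constrained rows: value_r = c0[r] + Ccoef[r, ] %*% theta
  nCon <- length(con)
  c0 <- numeric(nCon)
  Ccoef <- matrix(0, nCon, q)
  if (nCon) {
    exprs <- lapply(pars$expr[con], function(e) parse(text = e)[[1]])
    evalAt <- function(th) {
      env <- list2env(as.list(setNames(th, labels)), parent = baseenv())
      vapply(exprs, eval, numeric(1), envir = env)
    }
    c0 <- evalAt(rep(0, q))
    for (t in seq_len(q)) {
      e <- rep(0, q); e[t] <- 1
      Ccoef[, t] <- evalAt(e) - c0
    }
    ## affine check at a deterministic probe point
    probe <- sin(seq_len(q))
    if (max(abs(evalAt(probe) - (c0 + Ccoef %*% probe))) > 1e-10)
      stop("constrained expressions must be affine in the free labels")
  }

  list(
    vars = vars, m = m, p = length(obsIdx), obsIdx = obsIdx,
    q = q, labels = labels,
    B0 = B0, P0 = P0,
    freeRows = free, conRows = con,
    isBfree = isB[free], bIdxFree = bIdx[free],
    pIdx1Free = pIdx1[free], pIdx2Free = pIdx2[free],
    isBcon = isB[con], bIdxCon = bIdx[con],
    pIdx1Con = pIdx1[con], pIdx2Con = pIdx2[con],
    liFree = li[free], riFree = ri[free],
    liCon = li[con], riCon = ri[con],
    c0 = c0, Ccoef = Ccoef,
    varRowsFree = which(pars$status == "free" & pars$role == "variance")
  )
}

## theta -> (B, Psi)
evalMatrices <- function(cm, theta) {
  B <- cm$B0
  P <- cm$P0
  if (cm$q) {
    w <- cm$isBfree
    if (any(w)) B[cm$bIdxFree[w]] <- theta[w]
    if (any(!w)) {
      P[cm$pIdx1Free[!w]] <- theta[!w]
      P[cm$pIdx2Free[!w]] <- theta[!w]
    }
  }
  if (length(cm$conRows)) {
    v <- as.numeric(cm$c0 + cm$Ccoef %*% theta)
    w <- cm$isBcon
    if (any(w)) B[cm$bIdxCon[w]] <- v[w]
    if (any(!w)) {
      P[cm$pIdx1Con[!w]] <- v[!w]
      P[cm$pIdx2Con[!w]] <- v[!w]
    }
  }
  list(B = B, Psi = P)
}

## theta -> full-variable covariance and implied observed covariance
evalModel <- function(cm, theta) {
  mats <- evalMatrices(cm, theta)
  IB <- diag(cm$m) - mats$B
  M <- tryCatch(solve(IB), error = function(e)
    stop("singular I - B: the structural graph must be acyclic"))
  Cfull <- M %*% tcrossprod(mats$Psi, M)
  Cfull <- (Cfull + t(Cfull)) / 2
  list(B = mats$B, Psi = mats$Psi, M = M, Cfull = Cfull,
       Sigma = Cfull[cm$obsIdx, cm$obsIdx, drop = FALSE])
}

#' Resolve a parameter table at given free-parameter values
#'
#' Evaluates every constrained row from its affine expression, copies fixed
#' rows verbatim, and returns the full coefficient matrix B, the exogenous
#' covariance matrix Psi, and the observed-variable selection matrix G of
#' the all-endogenous representation.
#'
#' @param table a [ParameterTable-class].
#' @param theta numeric vector of free-parameter values (length q), in the
#'   table's free-label order; names are ignored.
#' @return list with elements `B`, `Psi` (both over all model variables)
#'   and `G` (p x m selection matrix).
#' @export
resolveConstraints <- function(table, theta = numeric()) {
  cm <- compileTable(table)
  if (length(theta) != cm$q)
    stop(sprintf("theta must have length %d (the number of free labels)", cm$q))
  mats <- evalMatrices(cm, as.numeric(theta))
  G <- matrix(0, cm$p, cm$m, dimnames = list(table@observed, cm$vars))
  G[cbind(seq_len(cm$p), cm$obsIdx)] <- 1
  list(B = mats$B, Psi = mats$Psi, G = G)
}

#' Model-implied covariance matrix
#'
#' Sigma = G (I - B)^-1 Psi (I - B)^-T G', the covariance of the observed
#' variables implied by the all-endogenous coefficient matrix B and
#' exogenous covariance Psi.
#'
#' @param B coefficient matrix over all model variables.
#' @param Psi exogenous/residual covariance matrix, same dimension.
#' @param G selection matrix (p x m) picking the observed variables; by
#'   default the identity (all variables observed).
#' @return symmetric implied covariance matrix.
#' @export
impliedCovariance <- function(B, Psi, G = diag(nrow(B))) {
  m <- nrow(B)
  IB <- diag(m) - B
  M <- tryCatch(solve(IB), error = function(e)
    stop("singular I - B: cyclic model"))
  S <- G %*% M %*% tcrossprod(Psi, M) %*% t(G)
  S <- (S + t(S)) / 2
  if (!is.null(rownames(G)) && any(nzchar(rownames(G))))
    dimnames(S) <- list(rownames(G), rownames(G))
  else if (!is.null(colnames(B)) && nrow(G) == m)
    dimnames(S) <- dimnames(B)
  S
}

#' Implied moments of a parameter table
#'
#' Convenience wrapper: resolve the table at `theta` and return the implied
#' covariance matrix of the observed variables.
#'
#' @param table a [ParameterTable-class].
#' @param theta free-parameter values in free-label order.
#' @return implied covariance matrix (named).
#' @export
impliedMoments <- function(table, theta) {
  cm <- compileTable(table)
  if (length(theta) != cm$q)
    stop(sprintf("theta must have length %d", cm$q))
  ev <- evalModel(cm, as.numeric(theta))
  dimnames(ev$Sigma) <- list(table@observed, table@observed)
  ev$Sigma
}

#' Reduce sample moments to composite scores (two-step approach)
#'
#' Computes the covariance matrix of fixed-weight composite scores plus all
#' passthrough variables: T S T', where T stacks one weight row per block
#' and unit rows for the variables not involved in any block.
#'
#' @param moments a [SampleMoments-class].
#' @param blocks a list of [CompositeBlock-class] objects, or a
#'   [ModelSpec-class] whose blocks are used.
#' @param weights optional named list of weight vectors (one per block, in
#'   component order); default: unit weights (sums).
#' @return a [SampleMoments-class] over (composites, passthrough variables);
#'   the sample size and divisor are unchanged.
#' @export
twoStepReduce <- function(moments, blocks, weights = NULL) {
  stopifnot(is(moments, "SampleMoments"))
  if (is(blocks, "ModelSpec")) blocks <- blocks@blocks
  obs <- colnames(moments@S)
  comps <- unlist(lapply(blocks, function(b) b@components), use.names = FALSE)
  if (!all(comps %in% obs))
    stop(sprintf("weight refers to unknown variable(s): %s",
                 paste(setdiff(comps, obs), collapse = ", ")))
  passthrough <- setdiff(obs, comps)
  newNames <- c(vapply(blocks, function(b) b@name, character(1)), passthrough)
  Tm <- matrix(0, length(newNames), length(obs),
               dimnames = list(newNames, obs))
  for (b in blocks) {
    w <- if (!is.null(weights) && b@name %in% names(weights))
      weights[[b@name]] else rep(1, length(b@components))
    if (length(w) != length(b@components))
      stop(sprintf("block '%s': %d weights for %d components", b@name,
                   length(w), length(b@components)))
    Tm[b@name, b@components] <- w
  }
  Tm[cbind(passthrough, passthrough)] <- 1
  sampleMoments(Tm %*% moments@S %*% t(Tm), moments@n,
                divisor = moments@divisor)
}

vech <- function(S) S[lower.tri(S, diag = TRUE)]

#' Numerical local-identification check
#'
#' Computes the rank of the Jacobian of vech(Sigma(theta)) with respect to
#' the free parameters by central finite differences at `theta0` and at a
#' few randomly perturbed points.  A rank below q flags a locally
#' under-identified parameterization; the labels spanning the null space
#' are reported.
#'
#' @param table a [ParameterTable-class].
#' @param theta0 point of evaluation (free-label order); default: the
#'   table's start values with unit variances substituted for
#'   data-dependent starts.
#' @param nPerturb number of additional randomly perturbed evaluation
#'   points.
#' @param step relative finite-difference step.
#' @param tol singular values below `tol` times the largest are treated as
#'   zero.
#' @param seed seed for the perturbations (local; the global RNG state is
#'   restored).
#' @return list with elements `rank`, `q`, `identified`, `nullLabels`.
#' @export
checkLocalIdentification <- function(table, theta0 = NULL, nPerturb = 2,
                                     step = 1e-6, tol = 1e-8, seed = 1) {
  cm <- compileTable(table)
  if (is.null(theta0)) {
    theta0 <- table@pars$start[cm$freeRows]
    theta0[is.na(theta0)] <- 1
  }
  if (length(theta0) != cm$q) stop("theta0 must have length q")
  if (cm$q == 0L)
    return(list(rank = 0L, q = 0L, identified = TRUE,
                nullLabels = character()))
  jac <- function(th) {
    J <- matrix(0, cm$p * (cm$p + 1) / 2, cm$q)
    for (t in seq_len(cm$q)) {
      h <- step * (1 + abs(th[t]))
      tp <- th; tp[t] <- th[t] + h
      tm <- th; tm[t] <- th[t] - h
      J[, t] <- (vech(evalModel(cm, tp)$Sigma) -
                   vech(evalModel(cm, tm)$Sigma)) / (2 * h)
    }
    J
  }
  points <- list(theta0)
  if (nPerturb > 0)
    points <- c(points, withSeed(seed, lapply(seq_len(nPerturb), function(i)
      theta0 + 1e-2 * stats::rnorm(cm$q) * (1 + abs(theta0)))))
  best <- 0L
  nullLabels <- character()
  for (th in points) {
    sv <- svd(jac(th))
    r <- sum(sv$d > tol * max(sv$d, .Machine$double.eps))
    if (r > best) {
      best <- r
      nullLabels <- if (r < cm$q) {
        V <- sv$v[, seq(r + 1L, cm$q), drop = FALSE]
        cm$labels[apply(abs(V) > 0.1, 1, any)]
      } else character()
    }
  }
  list(rank = best, q = cm$q, identified = best == cm$q,
       nullLabels = nullLabels)
}

## evaluate code with a local seed; the global RNG state is restored
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
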