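## Normal-theory maximum-likelihood estimation of a ParameterTable against
## sample moments: F(theta) = ln|Sigma| + tr(S Sigma^-1) - ln|S| - p is
## minimized over the free parameters with all affine constraints resolved
## exactly at every evaluation (constrained labels substituted out, not
## handled by Lagrange multipliers).

## data-dependent default starts: sample variances for variance parameters,
## unit-weight combination variances for composite/excrescent variables,
## 0 for free composite loadings (free shared excrescent loadings start at
## the unit-weight value -1, set at build time)
startValues <- function(table, S) {
  pars <- table@pars
  free <- which(pars$status == "free")
  th <- pars$start[free]
  if (!any(is.na(th))) return(th)
  blocks <- table@blocks
  latents <- table@meta$latents
  for (k in which(is.na(th))) {
    i <- free[k]
    v <- pars$lhs[i]
    if (pars$role[i] == "variance") {
      th[k] <- 1
      if (v %in% rownames(S)) th[k] <- S[v, v]
      else {
        for (b in blocks) {
          if (v == b$name) {
            th[k] <- sum(S[b$components, b$components]); break
          }
          j <- match(v, b$excrescent)
          if (!is.na(j)) {
            r <- b$references[j]; s <- b$shared
            th[k] <- S[r, r] + S[s, s] - 2 * S[r, s]; break
          }
        }
        if (!is.null(latents) && nrow(latents) && v %in% latents$name) {
          ind <- latents$indicator[match(v, latents$name)]
          th[k] <- 0.5 * S[ind, ind]
        }
      }
    } else if (pars$role[i] == "covariance" &&
               pars$lhs[i] %in% rownames(S) && pars$rhs[i] %in% rownames(S)) {
      th[k] <- S[pars$lhs[i], pars$rhs[i]]
    } else th[k] <- 0
  }
  th
}

## F and its analytic gradient; S and logdetS fixed by closure
mlDiscrepancy <- function(cm, S) {
  p <- cm$p
  cS <- chol(S)
  logdetS <- 2 * sum(log(diag(cS)))
  objective <- function(theta) {
    ev <- tryCatch(evalModel(cm, theta), error = function(e) NULL)
    if (is.null(ev)) return(1e10)
    R <- tryCatch(chol(ev$Sigma), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    Sinv <- chol2inv(R)
    2 * sum(log(diag(R))) + sum(S * Sinv) - logdetS - p
  }
  gradient <- function(theta) {
    ev <- tryCatch(evalModel(cm, theta), error = function(e) NULL)
    if (is.null(ev)) return(rep(0, cm$q))
    R <- tryCatch(chol(ev$Sigma), error = function(e) NULL)
    if (is.null(R)) return(rep(0, cm$q))
    Sinv <- chol2inv(R)
    A <- Sinv - Sinv %*% S %*% Sinv            # dF = tr(A dSigma)
    Afull <- matrix(0, cm$m, cm$m)
    Afull[cm$obsIdx, cm$obsIdx] <- A
    GB <- 2 * t(ev$Cfull %*% Afull %*% ev$M)   # dF/dB[i,j]
    U <- t(ev$M) %*% Afull %*% ev$M            # dF/dPsi: 2U off-diag, U diag
    g <- numeric(cm$q)
    for (t in seq_len(cm$q)) {
      if (cm$isBfree[t]) g[t] <- GB[cm$bIdxFree[t]]
      else {
        i <- cm$liFree[t]; j <- cm$riFree[t]
        g[t] <- if (i == j) U[i, i] else 2 * U[i, j]
      }
    }
    if (length(cm$conRows)) {
      entry <- numeric(length(cm$conRows))
      for (r in seq_along(cm$conRows)) {
        if (cm$isBcon[r]) entry[r] <- GB[cm$bIdxCon[r]]
        else {
          i <- cm$liCon[r]; j <- cm$riCon[r]
          entry[r] <- if (i == j) U[i, i] else 2 * U[i, j]
        }
      }
      g <- g + as.numeric(crossprod(cm$Ccoef, entry))
    }
    g
  }
  list(objective = objective, gradient = gradient, logdetS = logdetS)
}

## derivative matrices dSigma/dtheta_t at theta (exact: the model is linear
## in each parameter given the others, constraints are affine)
dSigmaList <- function(cm, ev) {
  out <- vector("list", cm$q)
  for (t in seq_len(cm$q)) {
    dB <- matrix(0, cm$m, cm$m)
    dP <- matrix(0, cm$m, cm$m)
    if (cm$isBfree[t]) dB[cm$bIdxFree[t]] <- 1
    else { dP[cm$pIdx1Free[t]] <- 1; dP[cm$pIdx2Free[t]] <- 1 }
    if (length(cm$conRows)) {
      for (r in which(abs(cm$Ccoef[, t]) > 0)) {
        cf <- cm$Ccoef[r, t]
        if (cm$isBcon[r]) dB[cm$bIdxCon[r]] <- dB[cm$bIdxCon[r]] + cf
        else {
          dP[cm$pIdx1Con[r]] <- dP[cm$pIdx1Con[r]] + cf
          dP[cm$pIdx2Con[r]] <- dP[cm$pIdx2Con[r]] + cf
        }
      }
    }
    dC <- ev$M %*% dB %*% ev$Cfull
    dC <- dC + t(dC) + ev$M %*% dP %*% t(ev$M)
    out[[t]] <- dC[cm$obsIdx, cm$obsIdx, drop = FALSE]
  }
  out
}

## expected-information covariance matrix of theta-hat:
## acov = (2/n) * E^-1,  E_ij = tr(Sigma^-1 dSigma_i Sigma^-1 dSigma_j)
expectedInformationVcov <- function(cm, ev, n) {
  if (cm$q == 0L) return(matrix(0, 0, 0))
  Sinv <- chol2inv(chol(ev$Sigma))
  D <- dSigmaList(cm, ev)
  Ti <- lapply(D, function(d) Sinv %*% d)
  E <- matrix(0, cm$q, cm$q)
  for (i in seq_len(cm$q))
    for (j in i:cm$q)
      E[i, j] <- E[j, i] <- sum(Ti[[i]] * t(Ti[[j]]))
  V <- tryCatch(solve(E) * 2 / n, error = function(e) NULL)
  if (is.null(V)) {
    warning("singular expected information matrix: standard errors undefined")
    V <- matrix(NA_real_, cm$q, cm$q)
  }
  dimnames(V) <- list(cm$labels, cm$labels)
  V
}

## a few damped Newton steps with finite-difference Hessian of the analytic
## gradient, to drive the gradient norm to ~1e-9
newtonPolish <- function(theta, objective, gradient, maxSteps = 8,
                         gtol = 1e-9) {
  f <- objective(theta)
  for (it in seq_len(maxSteps)) {
    g <- gradient(theta)
    if (max(abs(g)) < gtol) break
    q <- length(theta)
    H <- matrix(0, q, q)
    for (t in seq_len(q)) {
      h <- 1e-6 * (1 + abs(theta[t]))
      tp <- theta; tp[t] <- theta[t] + h
      tm <- theta; tm[t] <- theta[t] - h
      H[, t] <- (gradient(tp) - gradient(tm)) / (2 * h)
    }
    H <- (H + t(H)) / 2
    ridge <- 0
    repeat {
      delta <- tryCatch(solve(H + ridge * diag(q), g),
                        error = function(e) NULL)
      if (!is.null(delta)) break
      ridge <- max(ridge * 10, 1e-8)
      if (ridge > 1e4) return(list(theta = theta, f = f))
    }
    stepped <- FALSE
    s <- 1
    for (ls in 1:12) {
      cand <- theta - s * delta
      fc <- objective(cand)
      if (fc <= f + 1e-14) {
        gc <- gradient(cand)
        if (fc < f || max(abs(gc)) < max(abs(g))) {
          theta <- cand; f <- fc; stepped <- TRUE
          break
        }
      }
      s <- s / 2
    }
    if (!stepped) break
  }
  list(theta = theta, f = f)
}

#' Fit a parameter table by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy
#' F = ln|Sigma(theta)| + tr(S Sigma(theta)^-1) - ln|S| - p
#' over the free parameters of a [ParameterTable-class], with affine
#' constraints substituted out exactly at every evaluation.  An unbiased
#' (divisor n - 1) covariance matrix is rescaled by (n - 1)/n before
#' fitting, so that the chi-square statistic n * F follows the divisor-n
#' convention.  Optimization uses a quasi-Newton run with analytic
#' gradients followed by damped Newton polishing; on failure up to
#' `control$retries` restarts from jittered starting values are attempted
#' (deterministically seeded).  Non-convergence sets the `converged` flag
#' rather than raising an error.
#'
#' @param table a [ParameterTable-class].
#' @param moments a [SampleMoments-class] covering the table's observed
#'   variables (any order).
#' @param start optional starting values (free-label order), overriding the
#'   defaults (0 for free composite loadings, sample-based variances).
#' @param se compute expected-information standard errors (default TRUE).
#' @param control list: `iter.max`, `eval.max`, `rel.tol` (passed to
#'   [stats::nlminb()]), `gradTol` (convergence criterion on the gradient
#'   max-norm, default 1e-6), `polishTol` (Newton polish target, default
#'   1e-9), `maxPolish`, `retries`, `retrySeed`.
#' @return a [FitResult-class].
#' @export
fitML <- function(table, moments, start = NULL, se = TRUE, control = list()) {
  stopifnot(is(table, "ParameterTable"), is(moments, "SampleMoments"))
  ctrl <- utils::modifyList(list(iter.max = 500, eval.max = 2000,
                                 rel.tol = 1e-12, gradTol = 1e-6,
                                 polishTol = 1e-9, maxPolish = 8,
                                 retries = 3, retrySeed = 42), control)
  moments <- mlScaled(moments)
  obs <- table@observed
  if (!all(obs %in% colnames(moments@S)))
    stop(sprintf("moments lack observed variable(s): %s",
                 paste(setdiff(obs, colnames(moments@S)), collapse = ", ")))
  S <- moments@S[obs, obs, drop = FALSE]
  moments <- sampleMoments(S, moments@n, divisor = "ml")
  n <- moments@n
  p <- length(obs)
  if (inherits(tryCatch(chol(S), error = function(e) e), "error"))
    stop("sample covariance matrix is not positive definite")
  if (n <= p)
    warning(sprintf("sample size (%g) does not exceed the number of variables (%d)",
                    n, p))

  cm <- compileTable(table)
  fns <- mlDiscrepancy(cm, S)

  if (cm$q == 0L) {
    ev <- evalModel(cm, numeric())
    Fhat <- fns$objective(numeric())
    Sigma <- ev$Sigma
    dimnames(Sigma) <- list(obs, obs)
    ll <- -(n / 2) * (p * log(2 * pi) + determinant(Sigma)$modulus[1] +
                        sum(S * chol2inv(chol(Sigma))))
    return(new("FitResult", estimates = setNames(numeric(), character()),
               se = setNames(numeric(), character()),
               vcovTheta = matrix(0, 0, 0), implied = Sigma,
               discrepancy = Fhat, logLik = as.numeric(ll), converged = TRUE,
               iterations = 0, gradNorm = 0, table = table,
               moments = moments))
  }

  theta0 <- if (is.null(start)) startValues(table, S) else as.numeric(start)
  if (length(theta0) != cm$q)
    stop(sprintf("start must have length %d", cm$q))

  best <- NULL
  iterations <- 0
  for (attempt in 0:ctrl$retries) {
    th0 <- theta0
    if (attempt > 0)
      th0 <- theta0 + withSeed(ctrl$retrySeed + attempt,
                               stats::rnorm(cm$q, 0, 0.1 * (1 + abs(theta0))))
    opt <- nlminb(th0, fns$objective, gradient = fns$gradient,
                  control = list(iter.max = ctrl$iter.max,
                                 eval.max = ctrl$eval.max,
                                 rel.tol = ctrl$rel.tol))
    iterations <- iterations + opt$iterations
    pol <- newtonPolish(opt$par, fns$objective, fns$gradient,
                        maxSteps = ctrl$maxPolish, gtol = ctrl$polishTol)
    gn <- max(abs(fns$gradient(pol$theta)))
    cand <- list(theta = pol$theta, f = pol$f, gradNorm = gn)
    if (is.null(best) || cand$f < best$f) best <- cand
    if (best$gradNorm <= ctrl$gradTol && best$f < 1e9) break
  }

  theta <- best$theta
  names(theta) <- cm$labels
  convergedFlag <- best$gradNorm <= ctrl$gradTol && best$f < 1e9
  ev <- evalModel(cm, theta)
  Sigma <- ev$Sigma
  dimnames(Sigma) <- list(obs, obs)
  Fhat <- best$f
  ll <- -(n / 2) * (p * log(2 * pi) + determinant(Sigma)$modulus[1] +
                      sum(S * chol2inv(chol(Sigma))))

  negVar <- cm$varRowsFree
  if (length(negVar)) {
    labs <- table@pars$label[negVar]
    est <- theta[match(labs, cm$labels)]
    if (any(est < 0, na.rm = TRUE))
      warning(sprintf("Heywood case: negative variance estimate for %s",
                      paste(labs[est < 0], collapse = ", ")))
  }

  if (se && convergedFlag) {
    V <- expectedInformationVcov(cm, ev, n)
    ses <- sqrt(pmax(diag(V), 0))
    ses[is.na(diag(V))] <- NA_real_
  } else {
    V <- matrix(NA_real_, cm$q, cm$q, dimnames = list(cm$labels, cm$labels))
    ses <- rep(NA_real_, cm$q)
  }
  names(ses) <- cm$labels

  new("FitResult", estimates = theta, se = ses, vcovTheta = V,
      implied = Sigma, discrepancy = Fhat, logLik = as.numeric(ll),
      converged = convergedFlag, iterations = iterations,
      gradNorm = best$gradNorm, table = table, moments = moments)
}

#' Composite weights from a loading matrix
#'
#' The weights that form each composite are the rows of the inverse of the
#' block's composite loading matrix (components in rows; composite of
#' interest, then excrescent variables, in columns).  The weights of the
#' composite of interest are the first row.
#'
#' @param Lambda square loading matrix with components as rownames.
#' @return named weight vector of the composite of interest, with the full
#'   inverted weight matrix attached as attribute `"W"`.
#' @export
weightsFromLoadings <- function(Lambda) {
  Lambda <- as.matrix(Lambda)
  if (nrow(Lambda) != ncol(Lambda)) stop("loading matrix must be square")
  W <- tryCatch(solve(Lambda), error = function(e)
    stop("degenerate solution: singular composite loading matrix"))
  w <- setNames(W[1L, ], rownames(Lambda))
  attr(w, "W") <- W
  w
}

resolveAt <- function(fit) {
  cm <- compileTable(fit@table)
  evalModel(cm, unname(fit@estimates))
}

blockInfo <- function(table, block) {
  if (is(block, "CompositeBlock")) block <- block@name
  for (b in table@blocks) if (b$name == block) return(b)
  stop(sprintf("no composite block named '%s' in the fitted table", block))
}

#' Recover composite weights from a fitted model
#'
#' For H-O variants, inverts the fitted k x k composite loading matrix of a
#' block and returns the first row; a unit-weight block recovers weights of
#' exactly 1.  For a one-step fit, the weights are the (partly fixed)
#' regression coefficients of the composite on its components.
#'
#' @param fit a [FitResult-class].
#' @param block block name or [CompositeBlock-class].
#' @return named weight vector over the block's components.
#' @export
recoverWeights <- function(fit, block) {
  stopifnot(is(fit, "FitResult"))
  b <- blockInfo(fit@table, block)
  ev <- resolveAt(fit)
  vars <- fit@table@variables
  if (fit@table@variant == "one_step") {
    w <- ev$B[match(b$name, vars), match(b$components, vars)]
    return(setNames(w, b$components))
  }
  Lambda <- ev$B[match(b$components, vars),
                 match(c(b$name, b$excrescent), vars), drop = FALSE]
  rownames(Lambda) <- b$components
  weightsFromLoadings(Lambda)
}

#' Standardize composite weights
#'
#' w_std_i = w_i * sd(x_i) / sd(c): the unstandardized weight multiplied by
#' the ratio of the component's standard deviation to the composite's
#' (model-implied) standard deviation.
#'
#' @param weights named unstandardized weight vector.
#' @param componentSds standard deviations of the components (same order).
#' @param compositeSd model-implied standard deviation of the composite.
#' @return standardized weight vector.
#' @export
standardizedWeights <- function(weights, componentSds, compositeSd) {
  if (any(componentSds <= 0)) stop("component sds must be positive")
  if (!is.finite(compositeSd) || compositeSd <= 0) {
    warning("Heywood case: nonpositive implied composite variance")
    return(setNames(rep(NA_real_, length(weights)), names(weights)))
  }
  weights * componentSds / compositeSd
}

#' Weights of all composite blocks, with delta-method standard errors
#'
#' @param fit a [FitResult-class] of an H-O or one-step table.
#' @param se add delta-method standard errors (needs a successful fit with
#'   an information matrix).
#' @return data.frame with columns `block`, `component`, `weight`, `se`,
#'   `weight.std`, `se.std`.
#' @export
blockWeights <- function(fit, se = TRUE) {
  stopifnot(is(fit, "FitResult"))
  tab <- fit@table
  if (!length(tab@blocks))
    stop("the fitted table has no composite blocks")
  cm <- compileTable(tab)
  vars <- tab@variables
  wfun <- function(theta) {
    ev <- evalModel(cm, theta)
    out <- numeric(0)
    for (b in tab@blocks) {
      if (tab@variant == "one_step")
        w <- ev$B[match(b$name, vars), match(b$components, vars)]
      else {
        Lambda <- ev$B[match(b$components, vars),
                       match(c(b$name, b$excrescent), vars), drop = FALSE]
        w <- solve(Lambda)[1L, ]
      }
      sdC <- sqrt(ev$Cfull[match(b$name, vars), match(b$name, vars)])
      sdX <- sqrt(diag(ev$Cfull)[match(b$components, vars)])
      ## components have zero error variance, so their full-model variance
      ## is the observed variance
      out <- c(out, w, w * sdX / sdC)
    }
    out
  }
  vals <- wfun(unname(fit@estimates))
  ses <- rep(NA_real_, length(vals))
  if (se && all(is.finite(fit@vcovTheta)) && nFree(fit) > 0) {
    J <- pracma::jacobian(wfun, unname(fit@estimates))
    ses <- sqrt(pmax(diag(J %*% fit@vcovTheta %*% t(J)), 0))
  }
  rows <- list()
  off <- 0L
  for (b in tab@blocks) {
    k <- length(b$components)
    rows[[b$name]] <- data.frame(
      block = b$name, component = b$components,
      weight = vals[off + seq_len(k)], se = ses[off + seq_len(k)],
      weight.std = vals[off + k + seq_len(k)],
      se.std = ses[off + k + seq_len(k)])
    off <- off + 2L * k
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standardized solution of a fit
#'
#' Standardizes every parameter row using the model-implied standard
#' deviations of all model variables: paths and loadings are multiplied by
#' sd(source)/sd(target), covariances become correlations, and variance
#' rows are expressed as proportions of the corresponding total variance.
#' Standard errors for the standardized estimates are obtained by the
#' delta method with numerically differentiated gradients.
#'
#' @param fit a [FitResult-class].
#' @param se add delta-method standard errors.
#' @return data.frame with columns `lhs`, `rhs`, `role`, `label`, `est`,
#'   `est.std`, and (with `se = TRUE`) `se.std`.
#' @export
standardizedSolution <- function(fit, se = TRUE) {
  stopifnot(is(fit, "FitResult"))
  core <- stdCore(fit@table)
  theta <- unname(fit@estimates)
  out <- core$frame(theta)
  if (se) {
    out$se.std <- NA_real_
    if (all(is.finite(fit@vcovTheta)) && nFree(fit) > 0) {
      J <- pracma::jacobian(core$stdAt, theta)
      out$se.std <- sqrt(pmax(diag(J %*% fit@vcovTheta %*% t(J)), 0))
    }
  }
  out
}

## standardization core shared with population-level summaries
stdCore <- function(tab) {
  cm <- compileTable(tab)
  pars <- tab@pars
  li <- match(pars$lhs, cm$vars)
  ri <- match(pars$rhs, cm$vars)
  isB <- pars$role %in% c("loading", "path")
  bIdx <- ri + (li - 1L) * cm$m
  pIdx <- li + (ri - 1L) * cm$m

  valuesAt <- function(theta) {
    ev <- evalModel(cm, theta)
    v <- numeric(nrow(pars))
    v[isB] <- ev$B[bIdx[isB]]
    v[!isB] <- ev$Psi[pIdx[!isB]]
    list(ev = ev, values = v)
  }
  stdAt <- function(theta) {
    va <- valuesAt(theta)
    dg <- diag(va$ev$Cfull)
    if (any(dg <= 0)) {
      bad <- cm$vars[which(dg <= 0)[1]]
      stop(sprintf("zero or negative implied variance for '%s'", bad))
    }
    sds <- sqrt(dg)
    out <- va$values
    out[isB] <- va$values[isB] * sds[li[isB]] / sds[ri[isB]]
    isCov <- pars$role == "covariance"
    out[isCov] <- va$values[isCov] / (sds[li[isCov]] * sds[ri[isCov]])
    isVar <- pars$role == "variance"
    out[isVar] <- va$values[isVar] / dg[li[isVar]]
    out
  }
  frame <- function(theta) {
    va <- valuesAt(theta)
    data.frame(lhs = pars$lhs, rhs = pars$rhs, role = pars$role,
               status = pars$status, label = pars$label,
               est = va$values, est.std = stdAt(theta))
  }
  list(cm = cm, valuesAt = valuesAt, stdAt = stdAt, frame = frame)
}

#' Export parameter estimates as CSV
#'
#' @param fit a [FitResult-class].
#' @param path output file path.
#' @return invisibly, the data.frame written.
#' @export
writeParameterEstimates <- function(fit, path) {
  std <- standardizedSolution(fit, se = TRUE)
  free <- fit@table@pars$status == "free"
  std$se <- NA_real_
  std$se[free] <- fit@se[match(std$label[free], names(fit@se))]
  out <- std[, c("lhs", "rhs", "role", "status", "label", "est", "se",
                 "est.std", "se.std")]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
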