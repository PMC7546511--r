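#' @include AllClasses.R design.R
NULL

# Per-condition sufficient statistics: condition means, within-condition
# scatter matrices and sample counts. The profiled likelihood depends on
# the data only through these, so fitting cost is independent of N.
.geneSuffStats <- function(gene) {
  Y <- gene@Y
  cond <- gene@condition
  L <- nrow(Y)
  lev <- levels(cond)
  J <- length(lev)
  K <- as.integer(table(cond)[lev])
  Ybar <- matrix(0, L, J)
  S <- array(0, dim = c(L, L, J))
  for (j in seq_len(J)) {
    Yj <- Y[, cond == lev[j], drop = FALSE]
    m <- rowMeans(Yj)
    Ybar[, j] <- m
    C <- Yj - m
    S[, , j] <- tcrossprod(C)
  }
  list(Ybar = Ybar, S = S, K = K, L = L, J = J, N = sum(K), levels = lev)
}

#' Profiled log-likelihood at fixed variance parameters
#'
#' For a given within-sample covariance (determined by \code{params} and
#' \code{structure}), profiles out the fixed effects by generalized least
#' squares and evaluates the multivariate-normal log-likelihood of the
#' gene's data:
#' \deqn{\hat\beta = (\sum_{jk} X_{jk}' \Sigma^{-1} X_{jk})^{-1}
#'   \sum_{jk} X_{jk}' \Sigma^{-1} Y_{jk},}
#' \deqn{\ell = -\tfrac12 \sum_{jk} [L \log 2\pi + \log|\Sigma| +
#'   r_{jk}' \Sigma^{-1} r_{jk}], \quad r_{jk} = Y_{jk} - X_{jk}\hat\beta.}
#'
#' @param params variance parameters (see \code{\link{buildCovariance}}).
#' @param gene a \linkS4class{GeneData}.
#' @param form model form (see \code{\link{designBlock}}).
#' @param structure covariance structure.
#' @return list with \code{logLik}, named \code{beta} and \code{vcov}
#'   (\eqn{(\sum X'\Sigma^{-1}X)^{-1}}).
#' @export
profileLoglik <- function(params, gene, form, structure) {
  stopifnot(is(gene, "GeneData"))
  ss <- .geneSuffStats(gene)
  Sigma <- buildCovariance(params, structure, ss$L)
  X <- lapply(seq_len(ss$J), function(j) designBlock(form, ss$J, ss$L, j))
  Xall <- do.call(rbind, X)
  if (qr(Xall)$rank < ncol(Xall))
    stop("rank-deficient design for gene ", gene@geneId)
  res <- .glsProfileCpp(Sigma, X, ss$Ybar, ss$S, ss$K, TRUE)
  if (!is.finite(res$logLik))
    stop("singular covariance for gene ", gene@geneId)
  beta <- as.vector(res$beta)
  names(beta) <- .betaNames(form, ss$J, ss$L)
  vcov <- res$vcov
  dimnames(vcov) <- list(names(beta), names(beta))
  list(logLik = res$logLik, beta = beta, vcov = vcov)
}

#' Optimizer settings for per-gene model fits
#'
#' @param reltol relative convergence tolerance on the log-likelihood.
#' @param maxit maximum quasi-Newton iterations.
#' @param fallback retry with Nelder-Mead from the best point if the
#'   quasi-Newton pass does not converge.
#' @param unstructuredMaxL refuse the unstructured covariance above this
#'   isoform count (its L(L+1)/2 parameters inflate type-I error and the
#'   fit becomes ill-conditioned).
#' @return a list of settings for \code{\link{fitGeneModel}}.
#' @export
fitControl <- function(reltol = 1e-8, maxit = 500L, fallback = TRUE,
                       unstructuredMaxL = 15L) {
  list(reltol = reltol, maxit = as.integer(maxit), fallback = fallback,
       unstructuredMaxL = as.integer(unstructuredMaxL))
}

# Moment-based starting values: covariance of the OLS residuals of the
# model form being fitted (computed from the sufficient statistics).
.initVarParams <- function(ss, structure, X) {
  L <- ss$L
  A <- matrix(0, ncol(X[[1L]]), ncol(X[[1L]]))
  b <- numeric(ncol(X[[1L]]))
  for (j in seq_len(ss$J)) {
    A <- A + ss$K[j] * crossprod(X[[j]])
    b <- b + ss$K[j] * crossprod(X[[j]], ss$Ybar[, j])
  }
  beta <- solve(A, b)
  Spool <- matrix(0, L, L)
  for (j in seq_len(ss$J)) {
    d <- ss$Ybar[, j] - drop(X[[j]] %*% beta)
    Spool <- Spool + ss$S[, , j] + ss$K[j] * tcrossprod(d)
  }
  Spool <- Spool / max(ss$N - 1, 1)
  if (!all(is.finite(Spool)) || all(Spool == 0)) Spool <- diag(1, L)
  dS <- pmax(diag(Spool), 1e-8)
  floorRho <- 1e-8 * mean(dS)
  off <- Spool[lower.tri(Spool)]
  sRho <- max(if (length(off)) mean(off) else floorRho, floorRho)
  s2 <- pmax(dS - sRho, 0.05 * dS)
  if (structure == "compound_symmetry") {
    c(mean(s2), sRho)
  } else if (structure == "unequal_variance") {
    c(s2, sRho)
  } else {
    ridge <- 1e-6 * sum(dS) / L
    C <- t(chol(Spool + diag(ridge + floorRho, L)))
    C[lower.tri(C, diag = TRUE)]
  }
}

#' Fit the split-plot mixed model for one gene
#'
#' Maximum-likelihood fit: the variance parameters are optimized
#' numerically (quasi-Newton on an unconstrained log/log-Cholesky
#' parameterization, numerical gradients, with a derivative-free fallback)
#' and the fixed effects are profiled out by generalized least squares at
#' each step. ML rather than REML is used throughout so that
#' likelihood-ratio tests between fixed-effect structures are valid.
#'
#' @param gene a \linkS4class{GeneData}.
#' @param form model form (see \code{\link{designBlock}}).
#' @param structure covariance structure (see
#'   \code{\link{buildCovariance}}).
#' @param control optimizer settings from \code{\link{fitControl}}.
#' @return a \linkS4class{FittedGeneModel}; on non-convergence the
#'   best-found values are returned with \code{converged = FALSE}.
#' @export
fitGeneModel <- function(gene, form = c("full", "null_type1", "null_type2"),
                         structure = c("unequal_variance",
                                       "compound_symmetry", "unstructured"),
                         control = fitControl()) {
  form <- match.arg(form)
  structure <- match.arg(structure)
  stopifnot(is(gene, "GeneData"))
  ss <- .geneSuffStats(gene)
  L <- ss$L; J <- ss$J
  p <- .paramCount(form, J, L)
  if (structure == "unstructured") {
    q <- L * (L + 1L) / 2L
    if (L > control$unstructuredMaxL || ss$N < q + p)
      stop("unstructured covariance refused for gene ", gene@geneId,
           " (L = ", L, ", N = ", ss$N,
           "): too many covariance parameters; use unequal_variance")
  }
  X <- lapply(seq_len(J), function(j) designBlock(form, J, L, j))
  if (qr(do.call(rbind, X) * rep(ss$K, each = L))$rank < p)
    stop("rank-deficient design for gene ", gene@geneId)

  structCode <- match(structure, .COV_STRUCTURES)
  negll <- function(theta)
    .negProfileLoglikCpp(theta, structCode, X, ss$Ybar, ss$S, ss$K)

  theta0 <- .paramsToTheta(.initVarParams(ss, structure, X), structure, L)
  opt <- stats::optim(theta0, negll, method = "BFGS",
                      control = list(reltol = control$reltol,
                                     maxit = control$maxit))
  evals <- opt$counts[["function"]]
  converged <- opt$convergence == 0L && opt$value < 1e9
  if (!converged && isTRUE(control$fallback)) {
    opt2 <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                         control = list(reltol = control$reltol,
                                        maxit = 10L * control$maxit))
    evals <- evals + opt2$counts[["function"]]
    if (opt2$value <= opt$value) opt <- opt2
    converged <- opt$convergence == 0L && opt$value < 1e9
  }

  params <- .thetaToParams(opt$par, structure, L)
  fin <- tryCatch({
    Sigma <- buildCovariance(params, structure, L)
    .glsProfileCpp(Sigma, X, ss$Ybar, ss$S, ss$K, TRUE)
  }, error = function(e) list(logLik = -Inf))
  if (!is.finite(fin$logLik)) {
    converged <- FALSE
    fin <- list(logLik = -Inf, beta = rep(NA_real_, p),
                vcov = matrix(NA_real_, p, p))
  }
  beta <- as.vector(fin$beta)
  names(beta) <- .betaNames(form, J, L)
  vc <- fin$vcov
  dimnames(vc) <- list(names(beta), names(beta))
  new("FittedGeneModel", geneId = gene@geneId, form = form,
      structure = structure, beta = beta, varParams = params,
      logLik = fin$logLik, vcov = vc, converged = converged,
      iterations = as.integer(evals), L = as.integer(L), J = as.integer(J))
}
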