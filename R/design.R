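#' @include AllClasses.R
NULL

# Free fixed-effect parameter counts under reference coding.
.paramCount <- function(form, J, L) {
  switch(form,
         full = J * L,
         null_type1 = L,
         null_type2 = J + L - 1L,
         stop("unknown model form: ", form))
}

.varParamCount <- function(structure, L) {
  switch(structure,
         compound_symmetry = 2L,
         unequal_variance = L + 1L,
         unstructured = L * (L + 1L) / 2L,
         stop("unknown covariance structure: ", structure))
}

.betaNames <- function(form, J, L) {
  nm <- "intercept"
  if (form %in% c("full", "null_type2") && J >= 2)
    nm <- c(nm, paste0("cond", 2:J))
  if (L >= 2) nm <- c(nm, paste0("iso", 2:L))
  if (form == "full" && J >= 2 && L >= 2)
    nm <- c(nm, as.vector(t(outer(2:J, 2:L, function(j, l)
      paste0("cond", j, ":iso", l)))))
  nm
}

#' Design matrix blocks for the split-plot isoform model
#'
#' Builds the L x p fixed-effect design block of one sample in condition
#' \code{j}. Under reference coding the first condition and first isoform
#' are baselines; columns are ordered intercept, condition dummies, isoform
#' dummies, condition-by-isoform interaction dummies. All samples within a
#' condition share the same block.
#'
#' @param form model form: \code{"full"} (intercept + isoform + condition +
#'   interaction), \code{"null_type1"} (intercept + isoform) or
#'   \code{"null_type2"} (intercept + isoform + condition).
#' @param J number of conditions, \code{L} number of isoforms.
#' @param j condition index of the sample (1-based; 1 = reference).
#' @return an L x p numeric matrix with named columns.
#' @export
#' @examples
#' designBlock("full", J = 2, L = 3, j = 2)
designBlock <- function(form, J, L, j) {
  form <- match.arg(form, .MODEL_FORMS)
  stopifnot(L >= 1, J >= 1, j >= 1, j <= J)
  if (form != "null_type1" && J < 2)
    stop("forms with condition effects need J >= 2")
  p <- .paramCount(form, J, L)
  X <- matrix(0, L, p, dimnames = list(NULL, .betaNames(form, J, L)))
  X[, "intercept"] <- 1
  if (form %in% c("full", "null_type2") && j >= 2)
    X[, paste0("cond", j)] <- 1
  if (L >= 2)
    for (l in 2:L) X[l, paste0("iso", l)] <- 1
  if (form == "full" && j >= 2 && L >= 2)
    for (l in 2:L) X[l, paste0("cond", j, ":iso", l)] <- 1
  X
}

#' @rdname designBlock
#' @param gene a \linkS4class{GeneData}; one block per condition level is
#'   returned (samples within a condition share the block).
#' @return for \code{buildDesignMatrix}, a named list of J blocks.
#' @export
buildDesignMatrix <- function(gene, form) {
  stopifnot(is(gene, "GeneData"))
  J <- nlevels(gene@condition)
  L <- nrow(gene@Y)
  out <- lapply(seq_len(J), function(j) designBlock(form, J, L, j))
  names(out) <- levels(gene@condition)
  out
}

#' Within-sample covariance of the L isoform measurements
#'
#' The unequal-variance structure is
#' \deqn{\Sigma = \mathrm{diag}(\sigma_1^2, \ldots, \sigma_L^2) +
#'   \sigma_\rho^2 J_L,}
#' i.e. isoform-specific residual variances plus a shared sample
#' random-effect variance on every entry. Compound symmetry constrains all
#' residual variances to be equal; the unstructured form is parameterized
#' by the lower-triangular Cholesky factor of \eqn{\Sigma} (column-wise,
#' diagonal first within each column).
#'
#' @param params variance parameters: \code{c(sigma2, sigmaRho2)} for
#'   compound symmetry; \code{c(sigma2_1, ..., sigma2_L, sigmaRho2)} for
#'   unequal variance; the L(L+1)/2 Cholesky entries for unstructured.
#' @param structure one of \code{"compound_symmetry"},
#'   \code{"unequal_variance"}, \code{"unstructured"}.
#' @param L isoform count.
#' @return symmetric positive-definite L x L matrix.
#' @export
#' @examples
#' buildCovariance(c(1, 4, 1), "unequal_variance", L = 2)  # [[2,1],[1,5]]
buildCovariance <- function(params, structure, L) {
  structure <- match.arg(structure, .COV_STRUCTURES)
  L <- as.integer(L)
  if (length(params) != .varParamCount(structure, L))
    stop("expected ", .varParamCount(structure, L), " parameters for ",
         structure, " with L = ", L)
  if (structure == "compound_symmetry") {
    if (params[1L] <= 0) stop("sigma2 must be positive")
    if (params[2L] < 0) stop("sigmaRho2 must be non-negative")
    Sigma <- diag(rep(params[1L], L), L) + params[2L]
  } else if (structure == "unequal_variance") {
    s2 <- params[seq_len(L)]
    if (any(s2 <= 0)) stop("all sigma2_l must be positive")
    if (params[L + 1L] < 0) stop("sigmaRho2 must be non-negative")
    Sigma <- diag(s2, L) + params[L + 1L]
  } else {
    C <- matrix(0, L, L)
    C[lower.tri(C, diag = TRUE)] <- params
    if (any(diag(C) <= 0)) stop("Cholesky diagonal must be positive")
    Sigma <- C %*% t(C)
  }
  Sigma
}

# Inverse-free parameterization used by the optimizer: all positivity
# constraints are absorbed by exp() so the search is unconstrained.
.thetaToParams <- function(theta, structure, L) {
  if (structure == "compound_symmetry") {
    c(exp(theta[1L]), exp(theta[2L]))
  } else if (structure == "unequal_variance") {
    c(exp(theta[seq_len(L)]), exp(theta[L + 1L]))
  } else {
    # log-Cholesky: diagonal entries (positions 1, L+1, 2L, ... in the
    # column-wise lower triangle) are logged, off-diagonals unconstrained
    idx <- .cholDiagIdx(L)
    params <- theta
    params[idx] <- exp(theta[idx])
    params
  }
}

.paramsToTheta <- function(params, structure, L) {
  if (structure %in% c("compound_symmetry", "unequal_variance")) {
    log(pmax(params, 1e-12))
  } else {
    idx <- .cholDiagIdx(L)
    theta <- params
    theta[idx] <- log(pmax(params[idx], 1e-12))
    theta
  }
}

.cholDiagIdx <- function(L) {
  pos <- matrix(0L, L, L)
  pos[lower.tri(pos, diag = TRUE)] <- seq_len(L * (L + 1L) / 2L)
  diag(pos)
}
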