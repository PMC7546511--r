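#' @include fit.R
NULL

#' Construct template parameters
#'
#' @param L isoform count.
#' @param betaFull named full-model fixed effects (intercept, cond2,
#'   iso2..isoL, cond2:iso2..cond2:isoL).
#' @param betaReduced named reduced-model fixed effects (intercept,
#'   iso2..isoL).
#' @param varFull,varReduced variance parameters for the two models.
#' @param structure covariance structure of the parameter sets.
#' @param source provenance label.
#' @return a \linkS4class{TemplateParams}.
#' @export
TemplateParams <- function(L, betaFull, betaReduced, varFull, varReduced,
                           structure = "unequal_variance",
                           source = "fitted-from-data") {
  new("TemplateParams", L = as.integer(L),
      betaFull = betaFull, betaReduced = betaReduced,
      varFull = as.numeric(varFull), varReduced = as.numeric(varReduced),
      structure = structure, source = source)
}

#' Built-in synthetic template parameter sets
#'
#' Loads one of the packaged template parameter fixtures with L = 5, 7 or
#' 11 isoforms. The fixtures are synthetic: their magnitudes are typical
#' of mixed-model fits to log-FPKM data (baseline around e^2 FPKM,
#' condition log fold changes of 0.5-0.8, residual variances near 1), not
#' estimates from any particular dataset. Users with their own data can
#' derive real templates via \code{\link{estimateTemplate}}.
#'
#' @param L 5, 7 or 11.
#' @return a \linkS4class{TemplateParams} with \code{source = "fixture"}.
#' @export
#' @examples
#' templateFixture(7)
templateFixture <- function(L = 7) {
  if (!L %in% c(5L, 7L, 11L))
    stop("fixtures are available for L = 5, 7 or 11")
  path <- system.file("extdata",
                      sprintf("template_synthetic_L%d.json", as.integer(L)),
                      package = "twoStepSplice", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  TemplateParams(L = j$L, betaFull = unlist(j$betaFull),
                 betaReduced = unlist(j$betaReduced),
                 varFull = j$varFull, varReduced = j$varReduced,
                 structure = j$structure, source = "fixture")
}

#' Estimate template parameters from a real gene
#'
#' Fits the full and the reduced (intercept + isoform) model to one
#' two-condition gene and packages both parameter sets for use as a
#' simulation template.
#'
#' @param gene a \linkS4class{GeneData} with exactly two conditions.
#' @param structure covariance structure (default unequal variances).
#' @param control optimizer settings.
#' @return a \linkS4class{TemplateParams} with
#'   \code{source = "fitted-from-data"}.
#' @export
estimateTemplate <- function(gene, structure = "unequal_variance",
                             control = fitControl()) {
  stopifnot(is(gene, "GeneData"))
  if (nlevels(gene@condition) != 2L)
    stop("templates require exactly two conditions")
  full <- fitGeneModel(gene, "full", structure, control)
  red <- fitGeneModel(gene, "null_type1", structure, control)
  if (!full@converged || !red@converged)
    stop("template fits for gene ", gene@geneId,
         " did not converge; consider templateFixture()")
  TemplateParams(L = full@L, betaFull = full@beta, betaReduced = red@beta,
                 varFull = full@varParams, varReduced = red@varParams,
                 structure = structure, source = "fitted-from-data")
}
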