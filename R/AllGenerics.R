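#' @include AllClasses.R
NULL

#' Accessors for twoStepSplice objects
#'
#' Small accessor generics: \code{geneId} returns the gene identifier,
#' \code{isoformIds} the ordered isoform identifiers, \code{nIsoforms} the
#' isoform count L, \code{conditions} the per-sample condition factor,
#' \code{abundanceScale} whether an \linkS4class{IsoformExperiment} is on
#' the raw or log scale.
#'
#' @param object a package object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases geneId isoformIds nIsoforms conditions abundanceScale
#' @examples
#' gd <- GeneData("g1", matrix(rnorm(12), 2, 6,
#'                dimnames = list(c("i1", "i2"), NULL)),
#'                factor(rep(c("a", "b"), each = 3)))
#' geneId(gd); nIsoforms(gd)
NULL

#' @rdname accessors
#' @export
setGeneric("geneId", function(object) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("isoformIds", function(object) standardGeneric("isoformIds"))
#' @rdname accessors
#' @export
setGeneric("nIsoforms", function(object) standardGeneric("nIsoforms"))
#' @rdname accessors
#' @export
setGeneric("conditions", function(object) standardGeneric("conditions"))
#' @rdname accessors
#' @export
setGeneric("abundanceScale", function(object) standardGeneric("abundanceScale"))

#' @rdname accessors
#' @export
setMethod("geneId", "GeneData", function(object) object@geneId)
#' @rdname accessors
#' @export
setMethod("geneId", "FittedGeneModel", function(object) object@geneId)
#' @rdname accessors
#' @export
setMethod("isoformIds", "GeneData", function(object) object@isoformIds)
#' @rdname accessors
#' @export
setMethod("nIsoforms", "GeneData", function(object) nrow(object@Y))
#' @rdname accessors
#' @export
setMethod("nIsoforms", "TemplateParams", function(object) object@L)
#' @rdname accessors
#' @export
setMethod("conditions", "GeneData", function(object) object@condition)
#' @rdname accessors
#' @export
setMethod("abundanceScale", "IsoformExperiment", function(object) object@scale)

#' @describeIn accessors fixed-effect estimates of a fitted model.
#' @export
setMethod("coef", "FittedGeneModel", function(object, ...) object@beta)

#' @describeIn accessors estimated covariance of the fixed-effect estimates.
#' @export
setMethod("vcov", "FittedGeneModel", function(object, ...) object@vcov)

#' @describeIn accessors maximised log-likelihood of a fitted model.
#' @export
setMethod("logLik", "FittedGeneModel", function(object, ...) {
  ll <- object@logLik
  attr(ll, "df") <- length(object@beta) + length(object@varParams)
  class(ll) <- "logLik"
  ll
})

#' Screening and confirmatory tables of a two-step result
#'
#' @param object a \linkS4class{TwoStepResult}.
#' @return a data.frame (see the class documentation for columns).
#' @export
setGeneric("screening", function(object) standardGeneric("screening"))
#' @rdname screening
#' @export
setGeneric("confirmatory", function(object) standardGeneric("confirmatory"))
#' @rdname screening
#' @export
setMethod("screening", "TwoStepResult", function(object) object@screening)
#' @rdname screening
#' @export
setMethod("confirmatory", "TwoStepResult", function(object) object@confirmatory)

setMethod("show", "GeneData", function(object) {
  cat("GeneData:", object@geneId, "\n",
      " ", nrow(object@Y), "isoforms x", ncol(object@Y), "samples;",
      nlevels(object@condition), "conditions (",
      paste(levels(object@condition), table(object@condition),
            sep = ":", collapse = ", "), ")\n")
})

setMethod("show", "FittedGeneModel", function(object) {
  cat("FittedGeneModel:", object@geneId,
      sprintf("[%s, %s]\n", object@form, object@structure),
      sprintf("  logLik %.4f, %d fixed effects, %d variance parameters, %s\n",
              object@logLik, length(object@beta), length(object@varParams),
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "TwoStepResult", function(object) {
  cat(sprintf("TwoStepResult (%s screen, %s confirmatory, %s FWER)\n",
              object@screenType, object@confirmatoryMethod, object@fwerMethod),
      sprintf("  alpha = %g; %d genes screened, %d passed; confirmatory level %g\n",
              object@alpha, object@M, object@R,
              if (object@M > 0) object@R * object@alpha / object@M else 0),
      sprintf("  %d confirmatory rejections\n",
              sum(object@confirmatory$rejected %in% TRUE)))
})

setMethod("show", "TemplateParams", function(object) {
  cat(sprintf("TemplateParams: L = %d isoforms (%s, %s)\n",
              object@L, object@structure, object@source),
      sprintf("  condition effect b2C = %.3f\n", object@betaFull[["cond2"]]))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: M = %d, m0 = {%s}, n = %d/condition, %s effects\n",
    object@M, paste(object@m0, collapse = ", "), object@n, object@effectSize),
    sprintf("  %d replicates, alpha = %g, %s screen, %s confirmatory, seed %d\n",
            object@replications, object@alpha, object@screenType,
            object@confirmatory, object@seed))
})

setMethod("show", "SimulationSummary", function(object) {
  cat("SimulationSummary over", object@config@replications, "replicates\n")
  print(object@summary, digits = 4, row.names = FALSE)
})
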