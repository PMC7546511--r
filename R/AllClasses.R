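#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.MODEL_FORMS <- c("full", "null_type1", "null_type2")
.COV_STRUCTURES <- c("compound_symmetry", "unequal_variance", "unstructured")
.FWER_METHODS <- c("bonferroni", "holm", "hochberg")

#' Container for an isoform-level abundance table
#'
#' An \code{IsoformExperiment} is a
#' \linkS4class{SummarizedExperiment} whose single assay
#' (\code{"abundance"}) holds per-sample isoform abundances (rows =
#' transcripts, columns = samples), with \code{rowData} columns
#' \code{gene_id} and \code{transcript_id}. The object tracks whether the
#' values are on the raw (FPKM/TPM) or the natural-log scale, and, when
#' logged, the pseudocount offset used so the transform is invertible.
#'
#' @slot scale either \code{"raw"} or \code{"log"}.
#' @slot logOffset positive pseudocount used by \code{\link{logTransform}};
#'   length zero while \code{scale == "raw"}.
#'
#' @seealso \code{\link{readIsoformTable}}, \code{\link{logTransform}},
#'   \code{\link{filterGenes}}, \code{\link{assembleGeneData}}
#' @export
setClass("IsoformExperiment",
  contains = "SummarizedExperiment",
  representation(scale = "character", logOffset = "numeric"))

setValidity("IsoformExperiment", function(object) {
  msg <- character(0)
  if (length(object@scale) != 1L || !object@scale %in% c("raw", "log"))
    msg <- c(msg, "scale must be \"raw\" or \"log\"")
  rd <- rowData(object)
  if (!all(c("gene_id", "transcript_id") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain gene_id and transcript_id")
  else {
    if (anyDuplicated(rd$transcript_id))
      msg <- c(msg, "transcript_id values must be unique")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample names must be unique")
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay must be named \"abundance\"")
  else {
    a <- assay(object, "abundance")
    if (identical(object@scale, "raw")) {
      if (any(is.na(a)) || any(a < 0))
        msg <- c(msg, "raw-scale abundances must be non-negative and non-missing")
      if (length(object@logOffset) != 0L)
        msg <- c(msg, "logOffset must be empty on the raw scale")
    } else {
      if (any(!is.finite(a)))
        msg <- c(msg, "log-scale abundances must be finite")
      if (length(object@logOffset) != 1L || object@logOffset <= 0)
        msg <- c(msg, "logOffset must be a single positive number on the log scale")
    }
  }
  if (length(msg)) msg else TRUE
})

#' One gene's model-ready data
#'
#' Holds the complete matrix of log-scale isoform abundances for a single
#' gene: one column per sample, one row per isoform, together with the
#' condition label of each sample. This is the unit on which the mixed
#' model is fitted.
#'
#' @slot geneId gene identifier.
#' @slot isoformIds ordered isoform (transcript) identifiers; row order of
#'   \code{Y}.
#' @slot Y numeric matrix, L isoforms x N samples, finite log abundances.
#' @slot condition factor of length N giving each sample's condition; the
#'   first level is the reference condition.
#'
#' @seealso \code{\link{assembleGeneData}}, \code{\link{fitGeneModel}}
#' @export
setClass("GeneData",
  representation(geneId = "character", isoformIds = "character",
                 Y = "matrix", condition = "factor"))

setValidity("GeneData", function(object) {
  msg <- character(0)
  if (length(object@geneId) != 1L) msg <- c(msg, "geneId must be length 1")
  if (nrow(object@Y) != length(object@isoformIds))
    msg <- c(msg, "nrow(Y) must equal length(isoformIds)")
  if (ncol(object@Y) != length(object@condition))
    msg <- c(msg, "ncol(Y) must equal length(condition)")
  if (any(!is.finite(object@Y)))
    msg <- c(msg, "Y must be complete and finite")
  if (nlevels(object@condition) < 1L || any(table(object@condition) < 1L))
    msg <- c(msg, "every condition level needs at least one sample")
  if (length(msg)) msg else TRUE
})

#' A fitted per-gene mixed model
#'
#' Result of maximising the likelihood of the split-plot model for one gene
#' under one fixed-effect form and one covariance structure. Fixed effects
#' are reference-coded (first condition and first isoform are baselines).
#'
#' @slot geneId gene identifier.
#' @slot form one of \code{"full"}, \code{"null_type1"} (intercept +
#'   isoform), \code{"null_type2"} (adds condition main effect, no
#'   interaction).
#' @slot structure covariance structure: \code{"compound_symmetry"},
#'   \code{"unequal_variance"} or \code{"unstructured"}.
#' @slot beta named vector of fixed-effect estimates.
#' @slot varParams variance parameters on their natural scale (see
#'   \code{\link{buildCovariance}}).
#' @slot logLik maximised log-likelihood.
#' @slot vcov estimated covariance matrix of \code{beta}.
#' @slot converged optimizer status; non-convergent fits keep best-found
#'   values and are excluded from downstream p-values.
#' @slot iterations number of objective evaluations used.
#' @slot L,J isoform and condition counts.
#' @export
setClass("FittedGeneModel",
  representation(geneId = "character", form = "character",
                 structure = "character", beta = "numeric",
                 varParams = "numeric", logLik = "numeric", vcov = "matrix",
                 converged = "logical", iterations = "integer",
                 L = "integer", J = "integer"))

setValidity("FittedGeneModel", function(object) {
  msg <- character(0)
  if (!object@form %in% .MODEL_FORMS) msg <- c(msg, "unknown model form")
  if (!object@structure %in% .COV_STRUCTURES) msg <- c(msg, "unknown covariance structure")
  if (isTRUE(object@converged) && !is.finite(object@logLik))
    msg <- c(msg, "logLik must be finite when converged")
  p <- length(object@beta)
  if (!all(dim(object@vcov) == c(p, p)))
    msg <- c(msg, "vcov must be p x p")
  if (length(msg)) msg else TRUE
})

#' Result of the two-step OFDR-controlling procedure
#'
#' Gene-level screening decisions (BH at level \code{alpha}) and, for genes
#' that pass screening, per-isoform confirmatory decisions with the
#' family-wise error rate of each gene's L tests controlled at the reduced
#' level R*alpha/M.
#'
#' @slot alpha nominal OFDR level.
#' @slot M number of genes entering the screening BH correction
#'   (non-missing screening p-values).
#' @slot R number of genes passing screening.
#' @slot fwerMethod confirmatory FWER adjustment
#'   (\code{"bonferroni"}, \code{"holm"} or \code{"hochberg"}; the naive
#'   comparator uses \code{"simpleBH"}).
#' @slot screenType \code{"type1"} (expression or splicing) or
#'   \code{"type2"} (splicing only).
#' @slot confirmatoryMethod \code{"wald"}, \code{"ttest"} or \code{"anova"}.
#' @slot screening data.frame: gene_id, test_type, statistic, df, pvalue,
#'   fdr, passed.
#' @slot confirmatory data.frame, rows only for screened genes: gene_id,
#'   isoform_id, method, statistic, df, pvalue, threshold, rejected,
#'   fold_change.
#' @seealso \code{\link{twoStepProcedure}}, \code{\link{runTwoStep}}
#' @export
setClass("TwoStepResult",
  representation(alpha = "numeric", M = "integer", R = "integer",
                 fwerMethod = "character", screenType = "character",
                 confirmatoryMethod = "character",
                 screening = "data.frame", confirmatory = "data.frame"))

setValidity("TwoStepResult", function(object) {
  msg <- character(0)
  if (object@alpha <= 0 || object@alpha >= 1) msg <- c(msg, "alpha must be in (0,1)")
  if (object@R > object@M) msg <- c(msg, "R cannot exceed M")
  if (nrow(object@confirmatory)) {
    passed <- object@screening$gene_id[object@screening$passed %in% TRUE]
    if (!all(object@confirmatory$gene_id %in% passed))
      msg <- c(msg, "confirmatory rows exist only for genes passing screening")
  }
  if (length(msg)) msg else TRUE
})

#' Template parameters seeding the simulation engine
#'
#' Full-model and reduced-model parameter sets for one template gene with L
#' isoforms and two conditions: the reduced model (no condition effects)
#' generates null-hypothesis genes, the full model anchors the effect-size
#' intervals and covariance for false-null genes.
#'
#' @slot L isoform count.
#' @slot betaFull named fixed effects of the full model (2L values).
#' @slot betaReduced named fixed effects of the reduced model (L values).
#' @slot varFull,varReduced variance parameters (unequal-variance ordering:
#'   L residual variances then the sample random-effect variance).
#' @slot structure covariance structure both parameter sets refer to.
#' @slot source \code{"fitted-from-data"} or \code{"fixture"}.
#' @seealso \code{\link{templateFixture}}, \code{\link{estimateTemplate}}
#' @export
setClass("TemplateParams",
  representation(L = "integer", betaFull = "numeric", betaReduced = "numeric",
                 varFull = "numeric", varReduced = "numeric",
                 structure = "character", source = "character"))

setValidity("TemplateParams", function(object) {
  msg <- character(0)
  L <- object@L
  if (length(object@betaFull) != 2L * L)
    msg <- c(msg, "betaFull must have 2L entries (J = 2 full model)")
  if (length(object@betaReduced) != L)
    msg <- c(msg, "betaReduced must have L entries")
  ok <- function(v) !inherits(try(buildCovariance(v, object@structure, L),
                                  silent = TRUE), "try-error")
  if (!ok(object@varFull)) msg <- c(msg, "varFull does not give a valid covariance")
  if (!ok(object@varReduced)) msg <- c(msg, "varReduced does not give a valid covariance")
  if (!object@source %in% c("fitted-from-data", "fixture"))
    msg <- c(msg, "source must be fitted-from-data or fixture")
  if (length(msg)) msg else TRUE
})

#' Description of a simulation scenario
#'
#' @slot M genes per simulated dataset.
#' @slot m0 number(s) of null-hypothesis genes; for each value, the
#'   remaining M - m0 genes split evenly into fully and partially
#'   differential genes, so M - m0 must be even.
#' @slot n samples per condition.
#' @slot effectSize \code{"small"}, \code{"medium"} or \code{"large"}
#'   effect-size interval scheme.
#' @slot replications simulated datasets per m0.
#' @slot alpha nominal OFDR level of the two-step procedure.
#' @slot template \linkS4class{TemplateParams} seeding generation.
#' @slot fwerMethods confirmatory FWER adjustments evaluated.
#' @slot confirmatory \code{"wald"} or \code{"ttest"} confirmatory test.
#' @slot screenType screening test type (\code{"type1"} default).
#' @slot structure covariance structure used for fitting.
#' @slot seed master seed; replicate seeds derive from it deterministically.
#' @seealso \code{\link{simulationConfig}}, \code{\link{runSimulationStudy}}
#' @export
setClass("SimulationConfig",
  representation(M = "integer", m0 = "integer", n = "integer",
                 effectSize = "character", replications = "integer",
                 alpha = "numeric", template = "TemplateParams",
                 fwerMethods = "character", confirmatory = "character",
                 screenType = "character", structure = "character",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (any(object@m0 < 0L) || any(object@m0 > object@M))
    msg <- c(msg, "m0 must lie in [0, M]")
  if (any((object@M - object@m0) %% 2L != 0L))
    msg <- c(msg, "M - m0 must be even (half full, half partial FNHGs)")
  if (object@alpha <= 0 || object@alpha >= 1) msg <- c(msg, "alpha must be in (0,1)")
  if (!object@effectSize %in% c("small", "medium", "large"))
    msg <- c(msg, "effectSize must be small, medium or large")
  if (!all(object@fwerMethods %in% .FWER_METHODS))
    msg <- c(msg, "unknown FWER method")
  if (!object@confirmatory %in% c("wald", "ttest"))
    msg <- c(msg, "confirmatory must be wald or ttest")
  if (object@n < 2L) msg <- c(msg, "need n >= 2 samples per condition")
  if (length(msg)) msg else TRUE
})

#' Averaged operating characteristics of a simulation study
#'
#' @slot summary data.frame with one row per (m0, method): mean OFDR,
#'   power(I), power(II) across replicates with Monte-Carlo standard errors.
#' @slot replicates per-replicate metrics underlying the summary.
#' @slot config the \linkS4class{SimulationConfig} that produced it.
#' @export
setClass("SimulationSummary",
  representation(summary = "data.frame", replicates = "data.frame",
                 config = "SimulationConfig"))
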