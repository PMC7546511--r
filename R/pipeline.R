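#' @include testing.R
NULL

#' Fit screening models for a set of genes
#'
#' Fits the full model and the null model implied by the screening type to
#' every gene and assembles the gene-level likelihood-ratio screening
#' table.
#'
#' @param genes list of \linkS4class{GeneData}
#'   (from \code{\link{assembleGeneData}} or \code{\link{simulateDataset}}).
#' @param type screening test: \code{"type1"} (differential expression or
#'   splicing; full vs intercept + isoform) or \code{"type2"} (differential
#'   splicing only; full vs no-interaction model).
#' @param structure covariance structure for all fits.
#' @param control optimizer settings (\code{\link{fitControl}}).
#' @return list with \code{screening} (data.frame, one row per gene) and
#'   \code{fits} (per-gene list of \code{full} and \code{null} fits).
#' @export
screenGenes <- function(genes, type = c("type1", "type2"),
                        structure = "unequal_variance",
                        control = fitControl()) {
  type <- match.arg(type)
  nullForm <- if (type == "type1") "null_type1" else "null_type2"
  fits <- lapply(genes, function(g) {
    list(full = fitGeneModel(g, "full", structure, control),
         null = fitGeneModel(g, nullForm, structure, control))
  })
  screening <- do.call(rbind, lapply(fits, function(f)
    lrtScreening(f$full, f$null)))
  rownames(screening) <- NULL
  list(screening = screening, fits = fits)
}

# Confirmatory p-value table for all genes up front (decisions are taken
# only for genes passing screening, which gives identical results).
.confirmatoryTable <- function(genes, fits, method) {
  do.call(rbind, lapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    L <- nrow(g@Y)
    do.call(rbind, lapply(seq_len(L), function(l) {
      if (method == "wald")
        waldIsoformTest(fits[[i]]$full, l, isoformId = g@isoformIds[l])
      else
        simpleIsoformTest(g, l, variant = method)
    }))
  }))
}

#' Run the full two-step analysis on per-gene data
#'
#' Convenience wrapper: fits the screening models, computes per-isoform
#' confirmatory p-values (Wald contrasts from the mixed model, or direct
#' t-tests / one-way ANOVA), and applies the two-step OFDR-controlling
#' procedure.
#'
#' @inheritParams screenGenes
#' @param alpha nominal OFDR level.
#' @param confirmatory \code{"wald"}, \code{"ttest"} or \code{"anova"}.
#' @param fwerMethod FWER adjustment within each screened gene.
#' @return a \linkS4class{TwoStepResult}.
#' @export
#' @examples
#' set.seed(1)
#' tpl <- templateFixture(5)
#' sim <- simulateDataset(tpl, M = 12, m0 = 8, n = 30)
#' res <- runTwoStep(sim$genes, alpha = 0.05)
#' res
runTwoStep <- function(genes, alpha = 0.05, type = c("type1", "type2"),
                       structure = "unequal_variance",
                       confirmatory = c("wald", "ttest", "anova"),
                       fwerMethod = c("hochberg", "holm", "bonferroni"),
                       control = fitControl()) {
  confirmatory <- match.arg(confirmatory)
  fwerMethod <- match.arg(fwerMethod)
  sg <- screenGenes(genes, type = type, structure = structure,
                    control = control)
  conf <- .confirmatoryTable(genes, sg$fits, confirmatory)
  twoStepProcedure(sg$screening, conf, alpha = alpha, method = fwerMethod,
                   confirmatoryMethod = confirmatory)
}
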