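#' @include simulate.R
NULL

#' Isoform expression profile plot
#'
#' Plots, for one gene, the per-condition mean log abundance of each
#' isoform: one line per condition across the isoform index. Parallel
#' lines indicate a pure expression shift (or no change); non-parallel
#' lines visualize differential splicing.
#'
#' @param gene a \linkS4class{GeneData}.
#' @param ... further arguments passed to \code{matplot}.
#' @return invisibly, the J x L matrix of condition mean profiles.
#' @export
plotIsoformProfile <- function(gene, ...) {
  stopifnot(is(gene, "GeneData"))
  means <- t(vapply(levels(gene@condition), function(lv)
    rowMeans(gene@Y[, gene@condition == lv, drop = FALSE]),
    numeric(nrow(gene@Y))))
  graphics::matplot(t(means), type = "b", pch = 19, lty = 1,
                    xlab = "isoform", ylab = "mean log abundance",
                    xaxt = "n", main = gene@geneId, ...)
  graphics::axis(1, at = seq_along(gene@isoformIds),
                 labels = gene@isoformIds, las = 2, cex.axis = 0.7)
  graphics::legend("topright", legend = rownames(means), bty = "n",
                   col = seq_len(nrow(means)), lty = 1, pch = 19)
  invisible(means)
}

#' Write profile plots for selected genes
#'
#' @param genes named list of \linkS4class{GeneData} (e.g. from
#'   \code{\link{assembleGeneData}}).
#' @param geneIds genes to plot.
#' @param outdir output directory; one PDF per gene.
#' @return invisibly, the written file paths.
#' @export
plotIsoformProfiles <- function(genes, geneIds, outdir = ".") {
  unknown <- setdiff(geneIds, names(genes))
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(geneIds, function(g) {
    f <- file.path(outdir, paste0("profile_", g, ".pdf"))
    grDevices::pdf(f, width = 6, height = 4.5)
    on.exit(grDevices::dev.off())
    plotIsoformProfile(genes[[g]])
    f
  }, character(1))
  invisible(paths)
}

#' Plot simulation operating characteristics against m0
#'
#' One panel per metric (OFDR, power(I), power(II)), one line per method,
#' with the nominal level marked on the OFDR panel.
#'
#' @param x a \linkS4class{SimulationSummary}.
#' @param metrics which metrics to draw.
#' @return invisibly, \code{NULL}.
#' @export
plotSimulationSummary <- function(x, metrics = c("ofdr", "powerI", "powerII")) {
  stopifnot(is(x, "SimulationSummary"))
  s <- x@summary
  op <- graphics::par(mfrow = c(1, length(metrics)))
  on.exit(graphics::par(op))
  methods <- unique(s$method)
  for (m in metrics) {
    graphics::matplot(
      unique(s$m0),
      vapply(methods, function(me) s[s$method == me, m],
             numeric(length(unique(s$m0)))),
      type = "b", pch = 19, lty = 1, xlab = "m0", ylab = m,
      ylim = c(0, max(s[[m]], x@config@alpha, na.rm = TRUE) * 1.1))
    if (m == "ofdr")
      graphics::abline(h = x@config@alpha, lty = 2)
    graphics::legend("topleft", legend = methods, bty = "n",
                     col = seq_along(methods), lty = 1, pch = 19, cex = 0.7)
  }
  invisible(NULL)
}
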