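#' @include simulate.R
NULL

#' Read and validate a run configuration
#'
#' A run configuration is a YAML (or JSON) file with the inputs and
#' settings of a screening / two-step run: \code{abundance} and
#' \code{metadata} paths, \code{outdir}, and optional \code{alpha},
#' \code{screenType}, \code{structure}, \code{confirmatory},
#' \code{fwerMethod}, \code{minIsoforms}, \code{minMeanAbundance},
#' \code{logOffset}, \code{reference} (reference condition) and
#' \code{seed}. Omitted fields take the defaults below.
#'
#' @param path configuration file.
#' @param overrides named list of fields overriding the file (mirrors
#'   command-line flags).
#' @return a validated named list with class \code{"RunConfig"}.
#' @export
readRunConfig <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  defaults <- list(alpha = 0.05, screenType = "type1",
                   structure = "unequal_variance", confirmatory = "wald",
                   fwerMethod = "hochberg", minIsoforms = 2,
                   minMeanAbundance = 1, logOffset = 1, reference = NULL,
                   seed = 1, outdir = ".")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[nm] <- defaults[nm]
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0,1)")
  for (nm in c("abundance", "metadata"))
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]]))
      stop(nm, " file not found: ", cfg[[nm]])
  class(cfg) <- "RunConfig"
  cfg
}

.loadGeneData <- function(config) {
  if (is.null(config$abundance) || is.null(config$metadata))
    stop("config must name 'abundance' and 'metadata' files")
  tab <- readIsoformTable(config$abundance)
  meta <- readSampleMetadata(config$metadata, reference = config$reference)
  tab <- filterGenes(tab, minIsoforms = config$minIsoforms,
                     minMeanAbundance = config$minMeanAbundance)
  tab <- logTransform(tab, offset = config$logOffset)
  assembleGeneData(tab, meta)
}

# Per-gene optimizer diagnostics in TSV-ready form.
.fitDiagnostics <- function(fits) {
  do.call(rbind, lapply(fits, function(f) do.call(rbind, lapply(f, function(m)
    data.frame(gene_id = m@geneId, form = m@form, structure = m@structure,
               logLik = m@logLik, converged = m@converged,
               iterations = m@iterations)))))
}

.writeManifest <- function(config, outdir, extra = list()) {
  manifest <- c(unclass(config), extra,
                list(package = "twoStepSplice",
                     version = as.character(utils::packageVersion("twoStepSplice"))))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
}

#' Run the screening stage from a configuration
#'
#' Reads, filters and log-transforms the abundance table, fits the
#' screening models per gene and writes \code{screening.tsv} (gene_id,
#' test_type, statistic, df, pvalue, fdr, passed) plus a reproducibility
#' manifest to the output directory.
#'
#' @param config a \code{RunConfig} from \code{\link{readRunConfig}} (or
#'   an equivalent named list).
#' @return invisibly, the screening data.frame.
#' @export
runScreen <- function(config) {
  genes <- .loadGeneData(config)
  message(length(genes), " genes enter screening")
  sg <- screenGenes(genes, type = config$screenType,
                    structure = config$structure)
  bh <- adjustBH(sg$screening$pvalue, config$alpha)
  sg$screening$fdr <- bh$adjusted
  sg$screening$passed <- bh$rejected
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(sg$screening, file.path(config$outdir, "screening.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(.fitDiagnostics(sg$fits),
                     file.path(config$outdir, "fit_diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(config, config$outdir,
                 list(genes = length(genes), R = sum(bh$rejected)))
  invisible(sg$screening)
}

#' Run the full two-step analysis from a configuration
#'
#' Screening plus confirmatory stage at the reduced level R*alpha/M;
#' writes \code{screening.tsv}, \code{confirmatory.tsv} and a manifest.
#'
#' @inheritParams runScreen
#' @return invisibly, the \linkS4class{TwoStepResult}.
#' @export
runTwoStepPipeline <- function(config) {
  genes <- .loadGeneData(config)
  message(length(genes), " genes enter screening")
  sg <- screenGenes(genes, type = config$screenType,
                    structure = config$structure)
  conf <- .confirmatoryTable(genes, sg$fits, config$confirmatory)
  res <- twoStepProcedure(sg$screening, conf, alpha = config$alpha,
                          method = config$fwerMethod,
                          confirmatoryMethod = config$confirmatory)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res@screening, file.path(config$outdir, "screening.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(.fitDiagnostics(sg$fits),
                     file.path(config$outdir, "fit_diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res@confirmatory,
                     file.path(config$outdir, "confirmatory.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(config, config$outdir,
                 list(genes = length(genes), M = res@M, R = res@R))
  invisible(res)
}

#' Run a simulation study from a configuration file
#'
#' The file mirrors \code{\link{simulationConfig}}: fields \code{M},
#' \code{m0} (scalar or list), \code{n}, \code{templateL} (5, 7 or 11,
#' selecting a packaged template fixture), \code{effectSize},
#' \code{replications}, \code{alpha}, \code{confirmatory},
#' \code{screenType}, \code{structure}, \code{seed}, \code{outdir}.
#' Writes \code{simulation_summary.tsv} (method x m0 x metric) and a
#' manifest.
#'
#' @param path YAML configuration file.
#' @param verbose progress output.
#' @return invisibly, the \linkS4class{SimulationSummary}.
#' @export
runSimulationPipeline <- function(path, verbose = FALSE) {
  cfg <- yaml::read_yaml(path)
  outdir <- if (is.null(cfg$outdir)) "." else cfg$outdir
  tpl <- templateFixture(if (is.null(cfg$templateL)) 7 else cfg$templateL)
  args <- cfg[intersect(names(cfg),
                        c("M", "m0", "n", "effectSize", "replications",
                          "alpha", "fwerMethods", "confirmatory",
                          "screenType", "structure", "seed"))]
  args$m0 <- unlist(args$m0)
  args$template <- tpl
  config <- do.call(simulationConfig, args)
  res <- runSimulationStudy(config, verbose = verbose)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res@summary,
                     file.path(outdir, "simulation_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(c(cfg, list(package = "twoStepSplice",
                               version = as.character(utils::packageVersion("twoStepSplice")))),
                   file.path(outdir, "manifest.yaml"))
  invisible(res)
}
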