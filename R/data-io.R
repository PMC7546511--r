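#' @include AllClasses.R
NULL

#' Construct an IsoformExperiment from a matrix
#'
#' @param abundance numeric matrix, transcripts x samples.
#' @param geneId character vector mapping each row to its gene.
#' @param transcriptId unique transcript identifiers (row names).
#' @param scale \code{"raw"} (FPKM/TPM) or \code{"log"}.
#' @param logOffset the pseudocount used if \code{scale = "log"}.
#' @return an \linkS4class{IsoformExperiment}.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' IsoformExperiment(m, geneId = c("g1", "g1"), transcriptId = rownames(m))
IsoformExperiment <- function(abundance, geneId, transcriptId = rownames(abundance),
                              scale = c("raw", "log"), logOffset = numeric(0)) {
  scale <- match.arg(scale)
  abundance <- as.matrix(abundance)
  rownames(abundance) <- transcriptId
  se <- SummarizedExperiment(
    assays = list(abundance = abundance),
    rowData = DataFrame(gene_id = as.character(geneId),
                        transcript_id = as.character(transcriptId)))
  new("IsoformExperiment", se, scale = scale, logOffset = logOffset)
}

#' Read an isoform abundance table
#'
#' Reads a tab-separated isoform abundance table in either long format
#' (columns \code{gene_id}, \code{transcript_id}, \code{sample_id},
#' \code{abundance}) or wide format (\code{gene_id}, \code{transcript_id},
#' then one column per sample). Values are taken to be raw-scale FPKM or
#' TPM. Input row and sample order is preserved.
#'
#' @param path path to a TSV file with a header row.
#' @param format \code{"auto"} (default; long is detected by the presence
#'   of a sample-id column), \code{"long"} or \code{"wide"}.
#' @param geneCol,txCol,sampleCol,valueCol column names for the long
#'   dialect; \code{geneCol}/\code{txCol} also name the wide id columns.
#' @return a raw-scale \linkS4class{IsoformExperiment}.
#' @export
readIsoformTable <- function(path, format = c("auto", "long", "wide"),
                             geneCol = "gene_id", txCol = "transcript_id",
                             sampleCol = "sample_id", valueCol = "abundance") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("abundance table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(geneCol, txCol))
    if (!col %in% colnames(tab))
      stop("required column '", col, "' is missing from ", path)
  if (format == "auto")
    format <- if (sampleCol %in% colnames(tab)) "long" else "wide"
  if (format == "long") {
    for (col in c(sampleCol, valueCol))
      if (!col %in% colnames(tab))
        stop("required column '", col, "' is missing from ", path)
    vals <- tab[[valueCol]]
    bad <- which(!is.finite(vals) | vals < 0)
    if (length(bad))
      stop("negative or missing abundance at data line ", bad[1L],
           " of ", path)
    key <- paste(tab[[geneCol]], tab[[txCol]], tab[[sampleCol]], sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (gene, transcript, sample) record at data line ",
           which(duplicated(key))[1L], " of ", path)
    tx <- unique(tab[[txCol]])
    samples <- unique(tab[[sampleCol]])
    gene_of <- tapply(tab[[geneCol]], tab[[txCol]], unique, simplify = FALSE)
    multi <- names(gene_of)[lengths(gene_of) > 1L]
    if (length(multi))
      stop("transcript '", multi[1L], "' maps to more than one gene")
    m <- matrix(NA_real_, length(tx), length(samples),
                dimnames = list(tx, samples))
    m[cbind(match(tab[[txCol]], tx), match(tab[[sampleCol]], samples))] <- vals
    if (anyNA(m))
      stop("long table is not complete: some (transcript, sample) pairs are absent")
    geneId <- unlist(gene_of)[tx]
  } else {
    sampleCols <- setdiff(colnames(tab), c(geneCol, txCol))
    if (!length(sampleCols))
      stop("wide table has no sample columns in ", path)
    if (anyDuplicated(tab[[txCol]]))
      stop("duplicate transcript_id at data line ",
           which(duplicated(tab[[txCol]]))[1L], " of ", path)
    m <- as.matrix(tab[, sampleCols, drop = FALSE])
    storage.mode(m) <- "double"
    bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
    if (nrow(bad))
      stop("negative or missing abundance at data line ", bad[1L, 1L],
           ", sample '", sampleCols[bad[1L, 2L]], "' of ", path)
    rownames(m) <- tab[[txCol]]
    geneId <- tab[[geneCol]]
  }
  IsoformExperiment(m, geneId = geneId, transcriptId = rownames(m),
                    scale = "raw")
}

#' Read a sample metadata table
#'
#' @param path TSV with header columns \code{sample_id} and
#'   \code{condition}.
#' @return data.frame with unique \code{sample_id} and a \code{condition}
#'   factor whose levels are sorted lexicographically (first level =
#'   reference condition).
#' @param reference optional condition label to use as the reference level.
#' @export
readSampleMetadata <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  for (col in c("sample_id", "condition"))
    if (!col %in% colnames(meta))
      stop("required column '", col, "' is missing from ", path)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in ", path)
  lev <- sort(unique(meta$condition))
  if (!is.null(reference)) {
    if (!reference %in% lev)
      stop("reference condition '", reference, "' not present in metadata")
    lev <- c(reference, setdiff(lev, reference))
  }
  meta$condition <- factor(meta$condition, levels = lev)
  meta
}

#' Log-transform raw abundances
#'
#' Replaces every abundance a by \code{log(a + offset)} (natural log) and
#' flags the object as log-scale, recording the offset so the transform can
#' be inverted exactly.
#'
#' @param x a raw-scale \linkS4class{IsoformExperiment}.
#' @param offset positive pseudocount; default 1.
#' @return the log-scale object.
#' @export
logTransform <- function(x, offset = 1) {
  stopifnot(is(x, "IsoformExperiment"))
  if (!identical(x@scale, "raw"))
    stop("table is already on the log scale")
  if (!is.numeric(offset) || length(offset) != 1L || offset <= 0)
    stop("offset must be a single positive number")
  a <- assay(x, "abundance")
  SummarizedExperiment::assay(x, "abundance") <- log(a + offset)
  x@scale <- "log"
  x@logOffset <- offset
  validObject(x)
  x
}

#' Filter low-abundance isoforms and single-isoform genes
#'
#' Applied on the raw scale, before \code{\link{logTransform}}. First drops
#' any isoform whose mean abundance across all samples falls below
#' \code{minMeanAbundance}; then drops any gene left with fewer than
#' \code{minIsoforms} isoforms (a single-isoform gene admits no splicing
#' contrast). The counts removed at each step are attached as attribute
#' \code{"dropped"} and reported via \code{message}.
#'
#' @param x a raw-scale \linkS4class{IsoformExperiment}.
#' @param minIsoforms minimum isoforms per retained gene (>= 2).
#' @param minMeanAbundance mean-across-samples abundance threshold
#'   (FPKM/TPM units; default 1).
#' @return the filtered object.
#' @export
filterGenes <- function(x, minIsoforms = 2, minMeanAbundance = 1) {
  stopifnot(is(x, "IsoformExperiment"))
  if (!identical(x@scale, "raw"))
    stop("filter on the raw scale, before logTransform()")
  if (minIsoforms < 2)
    stop("minIsoforms must be at least 2")
  a <- assay(x, "abundance")
  keepIso <- if (nrow(a)) rowMeans(a) >= minMeanAbundance else logical(0)
  droppedIso <- sum(!keepIso)
  x2 <- x[keepIso, ]
  g <- rowData(x2)$gene_id
  genesBefore <- length(unique(g))
  keepGene <- g %in% names(which(table(g) >= minIsoforms))
  droppedGenes <- genesBefore - length(unique(g[keepGene]))
  out <- x2[keepGene, ]
  attr(out, "dropped") <- c(isoforms = droppedIso, genes = droppedGenes)
  message(sprintf("filterGenes: dropped %d low-abundance isoforms, then %d genes with < %d isoforms",
                  droppedIso, droppedGenes, as.integer(minIsoforms)))
  out
}

#' Assemble per-gene model-ready data
#'
#' Splits a log-scale table into one \linkS4class{GeneData} per gene.
#' Isoforms are ordered lexicographically by transcript id and conditions
#' lexicographically by label (first level = reference) unless the metadata
#' factor already carries an explicit level order. Samples present in the
#' metadata but absent from the table are skipped with a warning;
#' samples present in the table but absent from the metadata are an error.
#'
#' @param x a log-scale \linkS4class{IsoformExperiment}.
#' @param meta data.frame with columns \code{sample_id} and
#'   \code{condition} (see \code{\link{readSampleMetadata}}).
#' @return named list of \linkS4class{GeneData}, one per gene.
#' @export
assembleGeneData <- function(x, meta) {
  stopifnot(is(x, "IsoformExperiment"))
  if (!identical(x@scale, "log"))
    stop("assembleGeneData expects a log-scale table; call logTransform() first")
  samples <- colnames(x)
  missingMeta <- setdiff(samples, meta$sample_id)
  if (length(missingMeta))
    stop("samples absent from metadata: ", paste(missingMeta, collapse = ", "))
  unused <- setdiff(meta$sample_id, samples)
  if (length(unused))
    warning("samples in metadata but not in table, skipped: ",
            paste(unused, collapse = ", "))
  meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
  cond <- meta$condition
  if (!is.factor(cond)) cond <- factor(cond, levels = sort(unique(cond)))
  cond <- droplevels(cond)
  a <- assay(x, "abundance")
  if (anyNA(a)) {
    bad <- which(is.na(a), arr.ind = TRUE)[1L, ]
    stop("missing isoform value for gene ",
         rowData(x)$gene_id[bad[1L]], ", sample ", samples[bad[2L]])
  }
  gid <- rowData(x)$gene_id
  out <- lapply(split(seq_len(nrow(a)), gid), function(idx) {
    ids <- rowData(x)$transcript_id[idx]
    o <- order(ids)
    GeneData(geneId = gid[idx][1L], Y = a[idx[o], , drop = FALSE],
             condition = cond, isoformIds = ids[o])
  })
  out[order(names(out))]
}

#' Construct a GeneData object
#'
#' @param geneId gene identifier.
#' @param Y numeric matrix of log abundances, isoforms x samples.
#' @param condition factor of per-sample condition labels.
#' @param isoformIds isoform identifiers (default: row names of \code{Y}).
#' @return a \linkS4class{GeneData}.
#' @export
GeneData <- function(geneId, Y, condition, isoformIds = rownames(Y)) {
  Y <- as.matrix(Y)
  if (is.null(isoformIds)) isoformIds <- paste0("iso", seq_len(nrow(Y)))
  rownames(Y) <- isoformIds
  if (!is.factor(condition))
    condition <- factor(condition, levels = sort(unique(condition)))
  new("GeneData", geneId = as.character(geneId), Y = Y,
      condition = droplevels(condition), isoformIds = as.character(isoformIds))
}

#' Flatten GeneData back to an abundance table
#'
#' Inverse of \code{\link{assembleGeneData}}: binds per-gene matrices back
#' into a single log-scale \linkS4class{IsoformExperiment}.
#'
#' @param genes list of \linkS4class{GeneData} sharing the same samples.
#' @param logOffset offset to record on the rebuilt object.
#' @return a log-scale \linkS4class{IsoformExperiment}.
#' @export
flattenGeneData <- function(genes, logOffset = 1) {
  stopifnot(length(genes) > 0)
  m <- do.call(rbind, lapply(genes, function(g) g@Y))
  gid <- unlist(lapply(genes, function(g) rep(g@geneId, nrow(g@Y))))
  tx <- unlist(lapply(genes, function(g) g@isoformIds))
  rownames(m) <- tx
  IsoformExperiment(m, geneId = gid, transcriptId = tx, scale = "log",
                    logOffset = logOffset)
}

#' Write an abundance table back to TSV
#'
#' @param x an \linkS4class{IsoformExperiment}.
#' @param path output file.
#' @param format \code{"wide"} (default) or \code{"long"}.
#' @return invisibly, \code{path}.
#' @export
writeIsoformTable <- function(x, path, format = c("wide", "long")) {
  format <- match.arg(format)
  a <- assay(x, "abundance")
  rd <- rowData(x)
  if (format == "wide") {
    out <- data.frame(gene_id = rd$gene_id, transcript_id = rd$transcript_id,
                      a, check.names = FALSE)
  } else {
    out <- data.frame(
      gene_id = rep(rd$gene_id, times = ncol(a)),
      transcript_id = rep(rd$transcript_id, times = ncol(a)),
      sample_id = rep(colnames(a), each = nrow(a)),
      abundance = as.vector(a))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
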