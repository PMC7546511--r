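#' @include templates.R pipeline.R
NULL

#' Create a simulation configuration
#'
#' Defaults reproduce the design of the method's operating-characteristic
#' study: M = 1000 genes per dataset, two conditions with n = 200 samples
#' each, 100 replicate datasets per m0, nominal level 0.05, Type 1
#' screening with the unequal-variance covariance, and all three FWER
#' adjustments evaluated side by side with the naive per-isoform BH
#' comparator.
#'
#' @param M genes per dataset.
#' @param m0 number(s) of null genes; M - m0 must be even.
#' @param n samples per condition.
#' @param template a \linkS4class{TemplateParams}
#'   (default \code{templateFixture(7)}).
#' @param effectSize \code{"small"}, \code{"medium"} or \code{"large"}.
#' @param replications datasets per m0.
#' @param alpha nominal OFDR level.
#' @param fwerMethods FWER adjustments to evaluate.
#' @param confirmatory \code{"wald"} or \code{"ttest"}.
#' @param screenType \code{"type1"} or \code{"type2"}.
#' @param structure covariance structure for fitting.
#' @param seed master seed.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(M = 1000, m0 = M, n = 200,
                             template = templateFixture(7),
                             effectSize = "medium", replications = 100,
                             alpha = 0.05,
                             fwerMethods = c("bonferroni", "holm", "hochberg"),
                             confirmatory = "wald", screenType = "type1",
                             structure = "unequal_variance", seed = 1) {
  new("SimulationConfig", M = as.integer(M), m0 = as.integer(m0),
      n = as.integer(n), template = template, effectSize = effectSize,
      replications = as.integer(replications), alpha = alpha,
      fwerMethods = fwerMethods, confirmatory = confirmatory,
      screenType = screenType, structure = structure, seed = as.integer(seed))
}

#' Draw fixed effects for one false-null gene
#'
#' The condition effect and every condition-by-isoform interaction are
#' drawn independently and uniformly from an interval anchored at the
#' template's full-model estimate b: for b > 0, [0, b] (small),
#' [b/2, 3b/2] (medium) or [b, 2b] (large); for b < 0 the mirrored
#' intervals [b, 0], [3b/2, b/2], [2b, b]. The intercept and the isoform
#' main effects are copied from the template unchanged. A zero template
#' coefficient gives a degenerate interval and a zero draw, with a
#' warning.
#'
#' @param template a \linkS4class{TemplateParams}.
#' @param scenario effect-size scenario.
#' @return named full-model fixed-effect vector (2L entries).
#' @export
drawEffectSizes <- function(template, scenario = c("small", "medium", "large")) {
  scenario <- match.arg(scenario)
  beta <- template@betaFull
  targets <- c("cond2", grep("^cond2:iso", names(beta), value = TRUE))
  for (nm in targets) {
    b <- beta[[nm]]
    if (b == 0) {
      warning("template coefficient ", nm, " is zero; drawing 0")
      next
    }
    bounds <- switch(scenario,
                     small = c(0, b),
                     medium = c(b / 2, 3 * b / 2),
                     large = c(b, 2 * b))
    beta[[nm]] <- stats::runif(1, min(bounds), max(bounds))
  }
  beta
}

#' Force the trailing isoforms of a gene to be null
#'
#' Converts a drawn full-model effect vector into a partially differential
#' gene: for isoforms l from floor((L+1)/2) + 1 through L the interaction
#' is set to the negative of the condition effect, which makes those
#' isoforms' true between-condition differences exactly zero while the
#' leading isoforms stay differential.
#'
#' @param effects named full-model fixed effects (2L entries).
#' @param L isoform count.
#' @return the modified effect vector.
#' @export
makePartialFnhg <- function(effects, L) {
  first0 <- floor((L + 1) / 2) + 1
  if (first0 <= L)
    for (l in first0:L)
      effects[[paste0("cond2:iso", l)]] <- -effects[["cond2"]]
  effects
}

# True between-condition mean differences per isoform under reference
# coding: cond2 for isoform 1, cond2 + cond2:isol otherwise.
.trueDiffs <- function(beta, L) {
  d <- rep(beta[["cond2"]], L)
  if (L >= 2)
    d[2:L] <- d[2:L] + beta[paste0("cond2:iso", 2:L)]
  unname(d)
}

#' Simulate one dataset of per-gene isoform abundances
#'
#' Generates M genes with L isoforms and two conditions of n samples each.
#' The first m0 genes are null genes drawn from the template's reduced
#' model (reduced fixed effects and reduced covariance); the remaining
#' genes split evenly into fully differential genes (all isoforms have
#' non-zero true differences) and partially differential genes (trailing
#' isoforms forced null), both with effects drawn by
#' \code{\link{drawEffectSizes}} and the full-model covariance. Uses the
#' current RNG state; seed it for reproducibility.
#'
#' @param template a \linkS4class{TemplateParams}.
#' @param M total genes; \code{m0} null genes (M - m0 even).
#' @param n samples per condition.
#' @param effectSize effect-size scenario for the differential genes.
#' @return list with \code{genes} (list of \linkS4class{GeneData}),
#'   \code{classes} (per-gene \code{"NHG"}, \code{"full_FNHG"} or
#'   \code{"partial_FNHG"}), \code{truth} (data.frame: gene_id,
#'   isoform_id, class, trueDiff, isDE) and \code{betas} (the realized
#'   generating fixed effects per gene).
#' @export
simulateDataset <- function(template, M, m0, n, effectSize = "medium") {
  stopifnot(is(template, "TemplateParams"), m0 >= 0, m0 <= M)
  if ((M - m0) %% 2 != 0)
    stop("M - m0 must be even (half full, half partial FNHGs)")
  L <- template@L
  nFNHG <- (M - m0) / 2
  classes <- rep(c("NHG", "full_FNHG", "partial_FNHG"),
                 times = c(m0, nFNHG, nFNHG))
  cond <- factor(rep(c("c1", "c2"), each = n))
  isoIds <- paste0("iso", seq_len(L))

  SigmaR <- buildCovariance(template@varReduced, template@structure, L)
  SigmaF <- buildCovariance(template@varFull, template@structure, L)
  cholR <- chol(SigmaR)
  cholF <- chol(SigmaF)
  Xred <- lapply(1:2, function(j) designBlock("null_type1", 2L, L, j))
  Xfull <- lapply(1:2, function(j) designBlock("full", 2L, L, j))

  genes <- vector("list", M)
  betas <- vector("list", M)
  diffs <- matrix(0, M, L)
  for (i in seq_len(M)) {
    if (classes[i] == "NHG") {
      beta <- template@betaReduced
      mu <- vapply(Xred, function(X) drop(X %*% beta), numeric(L))
      ch <- cholR
    } else {
      beta <- drawEffectSizes(template, effectSize)
      if (classes[i] == "partial_FNHG") beta <- makePartialFnhg(beta, L)
      diffs[i, ] <- .trueDiffs(beta, L)
      mu <- vapply(Xfull, function(X) drop(X %*% beta), numeric(L))
      ch <- cholF
    }
    E <- matrix(stats::rnorm(2 * n * L), 2 * n, L) %*% ch
    Y <- t(E) + mu[, rep(1:2, each = n)]
    genes[[i]] <- GeneData(sprintf("g%04d", i), Y, cond, isoformIds = isoIds)
    betas[[i]] <- beta
  }
  truth <- data.frame(
    gene_id = rep(sprintf("g%04d", seq_len(M)), each = L),
    isoform_id = rep(isoIds, times = M),
    class = rep(classes, each = L),
    trueDiff = as.vector(t(diffs)))
  truth$isDE <- truth$trueDiff != 0
  names(genes) <- names(betas) <- sprintf("g%04d", seq_len(M))
  list(genes = genes, classes = classes, truth = truth, betas = betas)
}

#' Score one analysed replicate against the generating truth
#'
#' A discovered gene (one passing screening) is a false discovery if it is
#' a null gene, or if any of its truly-null isoforms was rejected at the
#' confirmatory stage. The replicate's OFDR contribution is V/R (0 when
#' R = 0). power(I) is the proportion of truly differential isoforms in
#' the whole dataset that were rejected; power(II) is the proportion of
#' differential genes that pass screening with a correct decision on every
#' isoform (all differential isoforms rejected and no null isoform
#' rejected).
#'
#' @param sim output of \code{\link{simulateDataset}} (or anything with
#'   \code{$truth} in the same layout).
#' @param result a \linkS4class{TwoStepResult} over the same genes and
#'   isoforms.
#' @return one-row data.frame: R, V, ofdr, powerI, powerII plus the counts
#'   behind them.
#' @export
evaluateReplicate <- function(sim, result) {
  truth <- sim$truth
  stopifnot(is(result, "TwoStepResult"))
  scr <- result@screening
  if (!setequal(unique(truth$gene_id), scr$gene_id))
    stop("screening results and truth cover different genes")
  conf <- result@confirmatory
  key <- function(d) paste(d$gene_id, d$isoform_id, sep = "\r")
  if (nrow(conf) && !all(key(conf) %in% key(truth)))
    stop("confirmatory results name isoforms absent from the truth table")
  truth$rejected <- FALSE
  if (nrow(conf))
    truth$rejected[match(key(conf)[conf$rejected], key(truth))] <- TRUE

  passed <- scr$gene_id[scr$passed %in% TRUE]
  R <- length(passed)
  perGene <- split(truth, truth$gene_id)
  falseDisc <- vapply(passed, function(g) {
    d <- perGene[[g]]
    d$class[1L] == "NHG" || any(d$rejected & !d$isDE)
  }, logical(1))
  V <- sum(falseDisc)

  nDE <- sum(truth$isDE)
  powerI <- if (nDE > 0) sum(truth$rejected & truth$isDE) / nDE else NA_real_
  fnhg <- names(perGene)[vapply(perGene, function(d) d$class[1L] != "NHG",
                                logical(1))]
  correct <- vapply(fnhg, function(g) {
    g %in% passed && all(perGene[[g]]$rejected == perGene[[g]]$isDE)
  }, logical(1))
  powerII <- if (length(fnhg)) mean(correct) else NA_real_
  data.frame(R = R, V = V, ofdr = if (R > 0) V / R else 0,
             powerI = powerI, powerII = powerII,
             nDE = nDE, nFNHG = length(fnhg),
             correctFNHG = sum(correct))
}

# Vectorized Welch statistics for all isoforms of one two-condition gene.
.welchGene <- function(gene) {
  lev <- levels(gene@condition)
  stopifnot(length(lev) == 2L)
  Y1 <- gene@Y[, gene@condition == lev[1L], drop = FALSE]
  Y2 <- gene@Y[, gene@condition == lev[2L], drop = FALSE]
  n1 <- ncol(Y1); n2 <- ncol(Y2)
  m1 <- rowMeans(Y1); m2 <- rowMeans(Y2)
  v1 <- rowSums((Y1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((Y2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  data.frame(gene_id = gene@geneId, isoform_id = gene@isoformIds,
             method = "ttest", statistic = t, df = df,
             pvalue = 2 * stats::pt(-abs(t), df),
             fold_change = vapply(m2 - m1, .signedFoldChange, numeric(1)))
}

#' Naive isoform-by-isoform BH comparator
#'
#' The standard analysis the two-step procedure is compared against: a
#' Welch t-test for every isoform of every gene, BH correction applied
#' jointly across all M x L tests at level \code{alpha}, and a gene called
#' discovered when at least one of its isoforms is rejected. Results are
#' packaged in the \linkS4class{TwoStepResult} layout so
#' \code{\link{evaluateReplicate}} can score both procedures identically.
#'
#' @param genes list of two-condition \linkS4class{GeneData}.
#' @param alpha BH level.
#' @return a \linkS4class{TwoStepResult} with
#'   \code{fwerMethod = "simpleBH"}; the screening p-value reported per
#'   gene is its smallest isoform p-value and \code{passed} marks
#'   discovered genes.
#' @export
simpleBHComparator <- function(genes, alpha = 0.05) {
  tests <- do.call(rbind, lapply(genes, .welchGene))
  rownames(tests) <- NULL
  adj <- stats::p.adjust(tests$pvalue, method = "BH")
  tests$rejected <- adj <= alpha
  # realized BH cutoff: largest raw p among rejections (0 if none)
  cut <- if (any(tests$rejected)) max(tests$pvalue[tests$rejected]) else 0
  tests$threshold <- cut
  byGene <- split(tests, tests$gene_id)
  screening <- do.call(rbind, lapply(byGene, function(d) {
    data.frame(gene_id = d$gene_id[1L], test_type = "simpleBH",
               statistic = NA_real_, df = NA_real_,
               pvalue = min(d$pvalue), fdr = NA_real_,
               passed = any(d$rejected))
  }))
  screening <- screening[match(names(genes), screening$gene_id), ,
                         drop = FALSE]
  rownames(screening) <- NULL
  conf <- tests[tests$gene_id %in% screening$gene_id[screening$passed], ,
                drop = FALSE]
  new("TwoStepResult", alpha = alpha, M = as.integer(nrow(screening)),
      R = as.integer(sum(screening$passed)), fwerMethod = "simpleBH",
      screenType = "simpleBH", confirmatoryMethod = "ttest",
      screening = screening, confirmatory = conf)
}

#' Run a full simulation study
#'
#' For every m0 in the configuration and every replicate: simulate a
#' dataset, fit the screening models to each gene, run the two-step
#' procedure once per FWER method and the naive BH comparator, and score
#' each against the generating truth. Replicate seeds are derived
#' deterministically from the master seed, so two runs with the same
#' configuration are identical.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param verbose print a progress line per replicate.
#' @return a \linkS4class{SimulationSummary}; its \code{summary} slot
#'   holds mean OFDR / power(I) / power(II) with Monte-Carlo standard
#'   errors per (m0, method), its \code{replicates} slot the per-replicate
#'   metrics, including per-replicate counts of confirmatory families
#'   where the Bonferroni rejections are contained in Holm's and where
#'   Holm and Hochberg decide identically.
#' @export
runSimulationStudy <- function(config, verbose = FALSE) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  m0grid <- config@m0
  reps <- config@replications
  set.seed(config@seed)
  seedMat <- matrix(sample.int(2147483646L, reps * length(m0grid)),
                    nrow = reps)
  cmpMethods <- c("bonferroni", "holm", "hochberg")
  doFamilies <- all(cmpMethods %in% config@fwerMethods)
  rows <- list()
  for (gIdx in seq_along(m0grid)) {
    m0 <- m0grid[gIdx]
    for (r in seq_len(reps)) {
      set.seed(seedMat[r, gIdx])
      sim <- simulateDataset(config@template, config@M, m0, config@n,
                             config@effectSize)
      sg <- screenGenes(sim$genes, type = config@screenType,
                        structure = config@structure)
      conf <- .confirmatoryTable(sim$genes, sg$fits, config@confirmatory)
      tsrs <- lapply(config@fwerMethods, function(m)
        twoStepProcedure(sg$screening, conf, config@alpha, m,
                         confirmatoryMethod = config@confirmatory))
      names(tsrs) <- config@fwerMethods
      fam <- c(families = NA_real_, bonfSubsetHolm = NA_real_,
               holmEqHochberg = NA_real_)
      if (doFamilies) {
        rej <- lapply(cmpMethods, function(m) {
          d <- tsrs[[m]]@confirmatory
          split(d$rejected, d$gene_id)
        })
        names(rej) <- cmpMethods
        fams <- names(rej$hochberg)
        fam["families"] <- length(fams)
        fam["bonfSubsetHolm"] <- sum(vapply(fams, function(g)
          all(rej$holm[[g]] | !rej$bonferroni[[g]]), logical(1)))
        fam["holmEqHochberg"] <- sum(vapply(fams, function(g)
          identical(rej$holm[[g]], rej$hochberg[[g]]), logical(1)))
      }
      results <- c(tsrs, list(simpleBH = simpleBHComparator(sim$genes,
                                                           config@alpha)))
      for (m in names(results)) {
        met <- evaluateReplicate(sim, results[[m]])
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(m0 = m0, replicate = r, method = m), met,
          as.data.frame(as.list(fam)))
      }
      if (verbose)
        message(sprintf("m0 = %d, replicate %d/%d done", m0, r, reps))
    }
  }
  replicates <- do.call(rbind, rows)
  rownames(replicates) <- NULL
  agg <- function(v) c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
  pieces <- split(replicates,
                  list(replicates$m0, replicates$method), drop = TRUE)
  summary <- do.call(rbind, lapply(pieces, function(d) {
    o <- agg(d$ofdr); p1 <- agg(d$powerI); p2 <- agg(d$powerII)
    data.frame(m0 = d$m0[1L], method = d$method[1L],
               ofdr = o[1L], ofdrSE = o[2L],
               powerI = p1[1L], powerISE = p1[2L],
               powerII = p2[1L], powerIISE = p2[2L],
               replicates = nrow(d))
  }))
  summary <- summary[order(summary$m0, summary$method), , drop = FALSE]
  rownames(summary) <- NULL
  new("SimulationSummary", summary = summary, replicates = replicates,
      config = config)
}
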