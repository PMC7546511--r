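#' @include AllClasses.R fit.R
NULL

#' Gene-level likelihood-ratio screening test
#'
#' Compares a full-model fit with a nested null fit of the same gene and
#' covariance structure. Type 1 (full vs intercept + isoform) screens for
#' any condition effect on the gene's isoforms, i.e. differential
#' expression or differential splicing; Type 2 (full vs no-interaction)
#' screens for differential splicing only. The statistic
#' 2(l_full - l_null) is referred to a chi-square with degrees of freedom
#' equal to the difference in free fixed-effect counts: (J-1)L for Type 1,
#' (J-1)(L-1) for Type 2.
#'
#' @param fitFull full-model \linkS4class{FittedGeneModel}.
#' @param fitNull nested null fit (\code{null_type1} or \code{null_type2})
#'   of the same gene and structure.
#' @return one-row data.frame: gene_id, test_type, statistic, df, pvalue.
#'   If either fit failed to converge the p-value is \code{NA}.
#' @export
lrtScreening <- function(fitFull, fitNull) {
  stopifnot(is(fitFull, "FittedGeneModel"), is(fitNull, "FittedGeneModel"))
  if (fitFull@geneId != fitNull@geneId)
    stop("fits are for different genes")
  if (fitFull@structure != fitNull@structure)
    stop("fits use different covariance structures")
  if (fitFull@form != "full" || !fitNull@form %in% c("null_type1", "null_type2"))
    stop("need a full fit and a nested null fit")
  type <- if (fitNull@form == "null_type1") "type1" else "type2"
  df <- length(fitFull@beta) - length(fitNull@beta)
  if (!fitFull@converged || !fitNull@converged) {
    return(data.frame(gene_id = fitFull@geneId, test_type = type,
                      statistic = NA_real_, df = df, pvalue = NA_real_))
  }
  stat <- max(0, 2 * (fitFull@logLik - fitNull@logLik))
  data.frame(gene_id = fitFull@geneId, test_type = type, statistic = stat,
             df = df, pvalue = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Signed fold change on the natural scale from a log difference d:
# exp(d) for up-regulation, -exp(-d) for down, so |fc| >= 1 always.
.signedFoldChange <- function(d) {
  if (is.na(d)) return(NA_real_)
  if (d >= 0) exp(d) else -exp(-d)
}

#' Per-isoform confirmatory Wald contrast
#'
#' Tests whether isoform \code{l} is differentially expressed across
#' conditions using the full-model estimates: the J-1 contrasts
#' \eqn{\beta_j^C + \beta_{jl}^{IC} = 0} (reference coding; the
#' interaction term is absent for the reference isoform l = 1). The
#' statistic \eqn{(C\hat\beta)'(C V C')^{-1} C\hat\beta} is referred to a
#' chi-square with J-1 degrees of freedom, using the plug-in covariance of
#' the estimates (anticonservative at small n).
#'
#' @param fitFull converged full-model \linkS4class{FittedGeneModel}.
#' @param isoformIndex isoform position l (1-based, model row order).
#' @param isoformId optional identifier recorded in the output.
#' @return one-row data.frame: gene_id, isoform_id, method, statistic, df,
#'   pvalue, fold_change (signed; from the two-condition log difference,
#'   or the largest-magnitude condition contrast when J > 2).
#' @export
waldIsoformTest <- function(fitFull, isoformIndex, isoformId = NULL) {
  stopifnot(is(fitFull, "FittedGeneModel"))
  if (fitFull@form != "full") stop("Wald contrasts need the full model")
  J <- fitFull@J; L <- fitFull@L
  l <- as.integer(isoformIndex)
  stopifnot(l >= 1, l <= L)
  if (is.null(isoformId)) isoformId <- paste0("iso", l)
  if (!fitFull@converged) {
    return(data.frame(gene_id = fitFull@geneId, isoform_id = isoformId,
                      method = "wald", statistic = NA_real_, df = J - 1L,
                      pvalue = NA_real_, fold_change = NA_real_))
  }
  nm <- names(fitFull@beta)
  C <- matrix(0, J - 1L, length(nm), dimnames = list(NULL, nm))
  for (j in 2:J) {
    C[j - 1L, paste0("cond", j)] <- 1
    if (l >= 2) C[j - 1L, paste0("cond", j, ":iso", l)] <- 1
  }
  est <- drop(C %*% fitFull@beta)
  V <- C %*% fitFull@vcov %*% t(C)
  Vi <- try(solve(V), silent = TRUE)
  if (inherits(Vi, "try-error"))
    stop("singular contrast covariance for gene ", fitFull@geneId)
  stat <- drop(t(est) %*% Vi %*% est)
  d <- est[which.max(abs(est))]
  data.frame(gene_id = fitFull@geneId, isoform_id = isoformId,
             method = "wald", statistic = stat, df = J - 1L,
             pvalue = stats::pchisq(stat, J - 1L, lower.tail = FALSE),
             fold_change = .signedFoldChange(d))
}

#' Per-isoform t-test / one-way ANOVA confirmatory test
#'
#' Model-free alternative to \code{\link{waldIsoformTest}}: compares one
#' isoform's log abundances directly across conditions with a two-sample
#' t-test (Welch by default; \code{pooled = TRUE} for the equal-variance
#' version) or, for two or more conditions, a one-way ANOVA F-test.
#'
#' @param gene a \linkS4class{GeneData}.
#' @param isoformIndex isoform position (1-based).
#' @param variant \code{"ttest"} (requires two conditions) or
#'   \code{"anova"}.
#' @param pooled use the pooled-variance t-test instead of Welch.
#' @return one-row data.frame as in \code{\link{waldIsoformTest}}.
#' @export
simpleIsoformTest <- function(gene, isoformIndex,
                              variant = c("ttest", "anova"), pooled = FALSE) {
  variant <- match.arg(variant)
  stopifnot(is(gene, "GeneData"))
  l <- as.integer(isoformIndex)
  y <- gene@Y[l, ]
  cond <- gene@condition
  J <- nlevels(cond)
  if (any(table(cond) < 2L))
    stop("gene ", gene@geneId, ": every condition needs >= 2 samples")
  means <- tapply(y, cond, mean)
  d <- means[-1L] - means[1L]
  d <- d[which.max(abs(d))]
  if (variant == "ttest") {
    if (J != 2L) stop("t-test requires exactly two conditions")
    ht <- stats::t.test(y[cond == levels(cond)[2L]],
                        y[cond == levels(cond)[1L]], var.equal = pooled)
    stat <- unname(ht$statistic); df <- unname(ht$parameter)
  } else {
    ht <- stats::oneway.test(y ~ cond, var.equal = TRUE)
    stat <- unname(ht$statistic); df <- unname(ht$parameter[1L])
  }
  data.frame(gene_id = gene@geneId, isoform_id = gene@isoformIds[l],
             method = variant, statistic = stat, df = df,
             pvalue = ht$p.value, fold_change = .signedFoldChange(unname(d)))
}

#' Benjamini-Hochberg screening correction
#'
#' Step-up FDR control over the gene-level screening p-values. Missing
#' p-values (non-convergent fits) are excluded from the family size M and
#' reported; their adjusted values stay missing and they are never
#' rejected.
#'
#' @param pvalues numeric vector in [0,1], NAs allowed.
#' @param alpha target FDR level in (0,1).
#' @param countMissing count missing p-values in the family size M
#'   (more conservative) instead of excluding them.
#' @return list with \code{adjusted} (monotone BH q-values),
#'   \code{rejected} (logical), \code{M} (family size used) and
#'   \code{nMissing}.
#' @export
adjustBH <- function(pvalues, alpha = 0.05, countMissing = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0,1)")
  ok <- !is.na(pvalues)
  M <- if (countMissing) length(pvalues) else sum(ok)
  adjusted <- rep(NA_real_, length(pvalues))
  adjusted[ok] <- stats::p.adjust(pvalues[ok], method = "BH", n = max(M, 1L))
  rejected <- !is.na(adjusted) & adjusted <= alpha
  list(adjusted = adjusted, rejected = rejected, M = M,
       nMissing = sum(!ok))
}

#' Family-wise error control within one gene
#'
#' Controls the FWER of a gene's L confirmatory tests at \code{level} by
#' Bonferroni, Holm (step-down) or Hochberg (step-up). The realized
#' per-isoform comparison threshold is returned alongside the decisions
#' (for Bonferroni it is level/L for every isoform; for Holm and Hochberg
#' it is level/(L - rank + 1) at each p-value's ascending rank).
#'
#' @param pvalues the gene's isoform p-values.
#' @param method \code{"bonferroni"}, \code{"holm"} or \code{"hochberg"}.
#' @param level FWER level in (0,1).
#' @return list with \code{rejected} (logical) and \code{threshold}
#'   (numeric), both in input order; empty input gives empty output.
#' @export
adjustFWER <- function(pvalues, method = c("bonferroni", "holm", "hochberg"),
                       level = 0.05) {
  method <- match.arg(method)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must be a single number in (0,1)")
  n <- length(pvalues)
  if (n == 0L) return(list(rejected = logical(0), threshold = numeric(0)))
  adjusted <- stats::p.adjust(pvalues, method = method)
  rejected <- !is.na(adjusted) & adjusted <= level
  threshold <- if (method == "bonferroni") {
    rep(level / n, n)
  } else {
    rk <- rank(pvalues, ties.method = "first", na.last = "keep")
    level / (n - rk + 1)
  }
  list(rejected = rejected, threshold = threshold)
}

#' The two-step OFDR-controlling procedure
#'
#' Screening stage: BH at level \code{alpha} over the gene-level screening
#' p-values; R genes pass out of M tested. Confirmatory stage: for each
#' passing gene, the family of its L isoform p-values is tested with FWER
#' controlled at the reduced level R*alpha/M. Genes failing screening get
#' no confirmatory rejections, so confirmatory discoveries are always
#' nested within screened genes, and the expected proportion of falsely
#' discovered genes (any false rejection at either stage) is controlled
#' near \code{alpha}.
#'
#' @param screening data.frame with columns \code{gene_id} and
#'   \code{pvalue} (other columns, e.g. statistic/df/test_type, are carried
#'   through), one row per gene.
#' @param confirmatoryPvalues either a data.frame with columns
#'   \code{gene_id}, \code{isoform_id}, \code{pvalue} (extra columns
#'   carried through) covering at least every gene that can pass
#'   screening, or a named list of per-gene p-value vectors.
#' @param alpha nominal OFDR level.
#' @param method FWER method for the confirmatory families.
#' @param screenType,confirmatoryMethod labels recorded on the result.
#' @param countMissing see \code{\link{adjustBH}}.
#' @return a \linkS4class{TwoStepResult}.
#' @export
twoStepProcedure <- function(screening, confirmatoryPvalues, alpha = 0.05,
                             method = c("hochberg", "holm", "bonferroni"),
                             screenType = NULL, confirmatoryMethod = "wald",
                             countMissing = FALSE) {
  method <- match.arg(method)
  stopifnot(is.data.frame(screening),
            all(c("gene_id", "pvalue") %in% colnames(screening)))
  if (is.list(confirmatoryPvalues) && !is.data.frame(confirmatoryPvalues)) {
    confirmatoryPvalues <- do.call(rbind, lapply(
      names(confirmatoryPvalues), function(g) {
        p <- confirmatoryPvalues[[g]]
        ids <- names(p)
        if (is.null(ids)) ids <- paste0("iso", seq_along(p))
        data.frame(gene_id = g, isoform_id = ids, pvalue = as.numeric(p))
      }))
  }
  bh <- adjustBH(screening$pvalue, alpha, countMissing = countMissing)
  screening$fdr <- bh$adjusted
  screening$passed <- bh$rejected
  M <- bh$M
  R <- sum(bh$rejected)
  if (bh$nMissing > 0)
    message(bh$nMissing,
            " gene(s) with missing screening p-values excluded from BH (M = ",
            M, ")")
  level2 <- if (M > 0L) R * alpha / M else 0
  passedGenes <- screening$gene_id[screening$passed]
  conf <- confirmatoryPvalues[confirmatoryPvalues$gene_id %in% passedGenes, ,
                              drop = FALSE]
  if (R > 0L) {
    missing <- setdiff(passedGenes, conf$gene_id)
    if (length(missing))
      stop("no confirmatory p-values for screened gene(s): ",
           paste(missing, collapse = ", "))
    pieces <- lapply(split(conf, conf$gene_id), function(d) {
      fw <- adjustFWER(d$pvalue, method, level2)
      d$threshold <- fw$threshold
      d$rejected <- fw$rejected
      d
    })
    conf <- do.call(rbind, pieces)
    rownames(conf) <- NULL
    conf <- conf[order(match(conf$gene_id, screening$gene_id)), , drop = FALSE]
  } else {
    conf <- conf[0, , drop = FALSE]
    conf$threshold <- numeric(0)
    conf$rejected <- logical(0)
  }
  if (is.null(screenType))
    screenType <- if ("test_type" %in% colnames(screening))
      as.character(screening$test_type[1L]) else "type1"
  new("TwoStepResult", alpha = alpha, M = as.integer(M), R = as.integer(R),
      fwerMethod = method, screenType = screenType,
      confirmatoryMethod = confirmatoryMethod,
      screening = screening, confirmatory = conf)
}
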