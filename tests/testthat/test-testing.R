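# Screening LRTs, confirmatory tests and the multiplicity machinery.

makeFit <- function(geneId = "g", form = "full", logLik = 0, J = 2L, L = 3L,
                    structure = "unequal_variance", converged = TRUE,
                    beta = NULL, vcov = NULL) {
  nm <- twoStepSplice:::.betaNames(form, J, L)
  if (is.null(beta)) beta <- setNames(rep(0, length(nm)), nm)
  if (is.null(vcov)) vcov <- diag(length(nm))
  dimnames(vcov) <- list(nm, nm)
  q <- twoStepSplice:::.varParamCount(structure, L)
  new("FittedGeneModel", geneId = geneId, form = form, structure = structure,
      beta = beta, varParams = rep(1, q), logLik = logLik, vcov = vcov,
      converged = converged, iterations = 1L, L = L, J = J)
}

test_that("screening degrees of freedom are (J-1)L and (J-1)(L-1)", {
  for (J in 2:3) for (L in 2:8) {
    s1 <- lrtScreening(makeFit(J = J, L = L, logLik = 1),
                       makeFit(form = "null_type1", J = J, L = L))
    expect_equal(s1$df, (J - 1) * L)
    expect_identical(s1$test_type, "type1")
    s2 <- lrtScreening(makeFit(J = J, L = L, logLik = 1),
                       makeFit(form = "null_type2", J = J, L = L))
    expect_equal(s2$df, (J - 1) * (L - 1))
    expect_identical(s2$test_type, "type2")
  }
})

test_that("LRT statistic clips at zero and degenerates correctly", {
  s <- lrtScreening(makeFit(logLik = 2), makeFit(form = "null_type1", logLik = 2))
  expect_equal(s$statistic, 0)
  expect_equal(s$pvalue, 1)
  # non-convergent fits propagate a missing p-value
  s2 <- lrtScreening(makeFit(logLik = 5),
                     makeFit(form = "null_type1", converged = FALSE))
  expect_true(is.na(s2$pvalue))
  expect_error(lrtScreening(makeFit(), makeFit(form = "null_type1",
                                               structure = "compound_symmetry")),
               "structure")
  expect_error(lrtScreening(makeFit(), makeFit(geneId = "other",
                                               form = "null_type1")),
               "different genes")
})

test_that("J=2 Wald statistic is the squared contrast z-ratio", {
  set.seed(21)
  rg <- randomGene(3, c(8, 8))
  fit <- fitGeneModel(rg$gene, "full", "unequal_variance")
  for (l in 1:3) {
    w <- waldIsoformTest(fit, l)
    est <- coef(fit)[["cond2"]] +
      if (l >= 2) coef(fit)[[paste0("cond2:iso", l)]] else 0
    cn <- c("cond2", if (l >= 2) paste0("cond2:iso", l))
    se2 <- sum(vcov(fit)[cn, cn])
    expect_equal(w$statistic, est^2 / se2, tolerance = 1e-10)
    expect_equal(w$df, 1L)
  }
})

test_that("fold changes carry the sign convention and a zero contrast gives p = 1", {
  b <- setNames(rep(0, 6), twoStepSplice:::.betaNames("full", 2, 3))
  b["cond2"] <- log(5.5)
  fit <- makeFit(beta = b)
  w1 <- waldIsoformTest(fit, 1)
  expect_equal(w1$fold_change, 5.5, tolerance = 1e-12)
  b2 <- b; b2["cond2"] <- -log(14.65)
  w2 <- waldIsoformTest(makeFit(beta = b2), 1)
  expect_equal(w2$fold_change, -14.65, tolerance = 1e-12)
  expect_true(abs(w2$fold_change) >= 1)
  b3 <- b; b3["cond2"] <- 0
  w3 <- waldIsoformTest(makeFit(beta = b3), 1)
  expect_equal(w3$statistic, 0)
  expect_equal(w3$pvalue, 1)
})

test_that("simple isoform tests match the textbook Welch oracle", {
  set.seed(22)
  for (i in 1:10) {
    rg <- randomGene(2, c(sample(3:8, 1), sample(3:8, 1)))
    st <- simpleIsoformTest(rg$gene, 1, "ttest")
    lev <- levels(rg$gene@condition)
    x <- rg$gene@Y[1, rg$gene@condition == lev[1]]
    y <- rg$gene@Y[1, rg$gene@condition == lev[2]]
    o <- oracleWelch(x, y)
    expect_equal(st$statistic, o$statistic, tolerance = 1e-10)
    expect_equal(st$df, o$df, tolerance = 1e-10)
    expect_equal(st$pvalue, o$p, tolerance = 1e-10)
  }
  # with two groups, the classic one-way ANOVA is the squared pooled t-test
  g <- randomGene(2, c(4, 5))$gene
  expect_equal(simpleIsoformTest(g, 1, "anova")$pvalue,
               simpleIsoformTest(g, 1, "ttest", pooled = TRUE)$pvalue,
               tolerance = 1e-12)
  expect_error(simpleIsoformTest(randomGene(2, c(1, 3))$gene, 1), ">= 2")
})

test_that("BH matches the step-up rule, including the boundary case", {
  bh <- adjustBH(c(0.01, 0.04, 0.03, 0.05), alpha = 0.05)
  expect_true(all(bh$rejected))           # p_(4) = 0.05 <= 4*0.05/4
  bh2 <- adjustBH(rep(1, 5), 0.05)
  expect_false(any(bh2$rejected))
  expect_equal(bh2$adjusted, rep(1, 5))
  p <- c(0.001, NA, 0.2, 0.8)
  bh3 <- adjustBH(p, 0.05)
  expect_equal(bh3$M, 3L)
  expect_true(is.na(bh3$adjusted[2]))
  expect_false(bh3$rejected[2])
  expect_error(adjustBH(c(0.5), alpha = 1), "alpha")
  # adjusted values are monotone and dominate the raw p-values
  set.seed(23)
  for (i in 1:20) {
    p <- runif(sample(3:20, 1))
    a <- adjustBH(p, 0.05)$adjusted
    expect_true(all(a >= p - 1e-15))
    expect_true(all(diff(a[order(p)]) >= -1e-15))
  }
})

test_that("FWER methods match independent step-rule oracles and nest", {
  expect_equal(adjustFWER(c(0.01, 0.2), "bonferroni", 0.05)$rejected,
               c(TRUE, FALSE))
  expect_equal(adjustFWER(c(0.01, 0.04), "holm", 0.05)$rejected, c(TRUE, TRUE))
  expect_equal(adjustFWER(c(0.01, 0.04), "hochberg", 0.05)$rejected,
               c(TRUE, TRUE))
  # L = 1: all methods reduce to p <= level
  for (m in c("bonferroni", "holm", "hochberg")) {
    expect_true(adjustFWER(0.049, m, 0.05)$rejected)
    expect_false(adjustFWER(0.051, m, 0.05)$rejected)
  }
  expect_length(adjustFWER(numeric(0), "holm", 0.05)$rejected, 0L)
  set.seed(24)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    p <- round(runif(n), sample(1:3, 1))   # rounding forces ties
    lev <- runif(1, 0.01, 0.2)
    b <- adjustFWER(p, "bonferroni", lev)$rejected
    h <- adjustFWER(p, "holm", lev)$rejected
    hb <- adjustFWER(p, "hochberg", lev)$rejected
    expect_equal(b, oracleBonferroni(p, lev))
    expect_equal(h, oracleHolm(p, lev))
    expect_equal(hb, oracleHochberg(p, lev))
    expect_true(all(h[b]))    # bonferroni subset holm
    expect_true(all(hb[h]))   # holm subset hochberg
  }
})

test_that("the two-step procedure reproduces a hand-computed toy decision", {
  # M = 4 genes; BH at 0.05: sorted p (0.001, 0.002, 0.2, 0.9);
  # k* = 2 -> genes a, b pass; confirmatory level = 2*0.05/4 = 0.025.
  screening <- data.frame(gene_id = c("a", "b", "c", "d"),
                          pvalue = c(0.001, 0.2, 0.002, 0.9))
  conf <- list(
    a = c(i1 = 0.005, i2 = 0.5),    # bonferroni 0.025/2: reject i1 only
    b = c(i1 = 0.001, i2 = 0.001),
    c = c(i1 = 0.03, i2 = 0.012),   # reject i2 only
    d = c(i1 = 0.9, i2 = 0.9))
  res <- twoStepProcedure(screening, conf, alpha = 0.05, method = "bonferroni")
  expect_equal(res@M, 4L)
  expect_equal(res@R, 2L)
  expect_setequal(res@screening$gene_id[res@screening$passed], c("a", "c"))
  cf <- confirmatory(res)
  expect_setequal(unique(cf$gene_id), c("a", "c"))
  expect_equal(cf$threshold, rep(0.0125, 4))
  got <- cf$rejected[order(cf$gene_id, cf$isoform_id)]
  expect_equal(got, c(TRUE, FALSE, FALSE, TRUE))
  # a toy with no screening discoveries yields no confirmatory tests
  res0 <- twoStepProcedure(data.frame(gene_id = "a", pvalue = 0.9),
                           list(a = c(i1 = 0.001)), alpha = 0.05)
  expect_equal(res0@R, 0L)
  expect_equal(nrow(confirmatory(res0)), 0L)
})

test_that("the confirmatory family level is R*alpha/M", {
  screening <- data.frame(gene_id = letters[1:10],
                          pvalue = c(0.0001, 0.0002, rep(0.9, 8)))
  conf <- setNames(lapply(1:10, function(i) c(i1 = 0.004, i2 = 0.9)),
                   letters[1:10])
  res <- twoStepProcedure(screening, conf, alpha = 0.05, method = "bonferroni")
  expect_equal(res@R, 2L)
  # level 2*0.05/10 = 0.01; bonferroni threshold 0.005 per isoform
  expect_equal(unique(confirmatory(res)$threshold), 0.005)
  expect_true(all(confirmatory(res)$rejected ==
                    (confirmatory(res)$pvalue <= 0.005)))
})

test_that("shrinking alpha never adds rejections at either stage", {
  set.seed(25)
  screening <- data.frame(gene_id = sprintf("g%02d", 1:30),
                          pvalue = rbeta(30, 0.3, 2))
  conf <- setNames(lapply(1:30, function(i)
    setNames(rbeta(4, 0.3, 3), paste0("i", 1:4))), sprintf("g%02d", 1:30))
  r10 <- twoStepProcedure(screening, conf, alpha = 0.10, method = "hochberg")
  r05 <- twoStepProcedure(screening, conf, alpha = 0.05, method = "hochberg")
  p10 <- r10@screening$gene_id[r10@screening$passed]
  p05 <- r05@screening$gene_id[r05@screening$passed]
  expect_true(all(p05 %in% p10))
  k <- function(d) paste(d$gene_id, d$isoform_id)[d$rejected]
  expect_true(all(k(confirmatory(r05)) %in% k(confirmatory(r10))))
})
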