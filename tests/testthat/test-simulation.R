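# Dataset generation, truth bookkeeping and replicate scoring.

test_that("template fixtures load and validate for L = 5, 7, 11", {
  for (L in c(5, 7, 11)) {
    tpl <- templateFixture(L)
    expect_s4_class(tpl, "TemplateParams")
    expect_equal(nIsoforms(tpl), L)
    expect_length(tpl@betaFull, 2 * L)
    expect_length(tpl@betaReduced, L)
    expect_identical(tpl@source, "fixture")
  }
  expect_error(templateFixture(4), "5, 7 or 11")
})

test_that("templates can be re-estimated from data generated under them", {
  set.seed(31)
  tpl <- templateFixture(5)
  sim <- simulateDataset(tpl, M = 2, m0 = 2, n = 400)
  est <- estimateTemplate(sim$genes[[1]])
  expect_identical(est@source, "fitted-from-data")
  # reduced-model fixed effects recovered within generous sampling error
  expect_equal(unname(est@betaReduced), unname(tpl@betaReduced),
               tolerance = 0.2)
  expect_equal(unname(est@varReduced[1:5]), unname(tpl@varReduced[1:5]),
               tolerance = 0.35)
})

test_that("effect draws land in the scenario intervals, mirrored for negative anchors", {
  set.seed(32)
  tplPos <- templateFixture(7)
  b <- tplPos@betaFull
  intervals <- list(small = function(b) sort(c(0, b)),
                    medium = function(b) sort(c(b / 2, 3 * b / 2)),
                    large = function(b) sort(c(b, 2 * b)))
  targets <- c("cond2", paste0("cond2:iso", 2:7))
  for (sc in names(intervals)) {
    draws <- replicate(200, drawEffectSizes(tplPos, sc)[targets])
    for (nm in targets) {
      lim <- intervals[[sc]](b[[nm]])
      expect_true(all(draws[nm, ] >= lim[1] & draws[nm, ] <= lim[2]),
                  label = paste(sc, nm))
    }
  }
  # explicit anchors: b = 0.8 and b = -0.8
  tpl2 <- TemplateParams(2, c(intercept = 1, cond2 = 0.8, iso2 = -1,
                              `cond2:iso2` = -0.8),
                         c(intercept = 1, iso2 = -1),
                         c(1, 1, 0.2), c(1, 1, 0.2), source = "fixture")
  d <- replicate(500, drawEffectSizes(tpl2, "small"))
  expect_true(all(d["cond2", ] >= 0 & d["cond2", ] <= 0.8))
  expect_true(all(d["cond2:iso2", ] >= -0.8 & d["cond2:iso2", ] <= 0))
  dm <- replicate(500, drawEffectSizes(tpl2, "medium"))
  expect_true(all(dm["cond2", ] >= 0.4 & dm["cond2", ] <= 1.2))
  dl <- replicate(500, drawEffectSizes(tpl2, "large"))
  expect_true(all(dl["cond2", ] >= 0.8 & dl["cond2", ] <= 1.6))
  # untouched coefficients are copied verbatim
  expect_equal(unique(d["intercept", ]), 1)
  expect_equal(unique(d["iso2", ]), -1)
})

test_that("partial genes force exactly the trailing isoforms to null", {
  eff7 <- setNames(seq_len(14) / 10, twoStepSplice:::.betaNames("full", 2, 7))
  out7 <- makePartialFnhg(eff7, 7)
  forced <- paste0("cond2:iso", 5:7)        # floor(8/2)+1 = 5
  expect_equal(unname(out7[forced]), rep(-out7[["cond2"]], 3))
  d7 <- twoStepSplice:::.trueDiffs(out7, 7)
  expect_equal(d7[5:7], rep(0, 3))
  expect_true(all(d7[1:4] != 0))
  eff5 <- setNames(seq_len(10) / 10, twoStepSplice:::.betaNames("full", 2, 5))
  d5 <- twoStepSplice:::.trueDiffs(makePartialFnhg(eff5, 5), 5)
  expect_equal(which(d5 == 0), 4:5)         # floor(6/2)+1 = 4
})

test_that("simulated datasets carry a consistent truth table", {
  set.seed(33)
  tpl <- templateFixture(7)
  simNull <- simulateDataset(tpl, M = 10, m0 = 10, n = 5)
  expect_true(all(simNull$classes == "NHG"))
  expect_true(all(simNull$truth$trueDiff == 0))
  expect_false(any(simNull$truth$isDE))

  sim <- simulateDataset(tpl, M = 10, m0 = 0, n = 5)
  expect_equal(sum(sim$classes == "full_FNHG"), 5)
  expect_equal(sum(sim$classes == "partial_FNHG"), 5)
  tt <- sim$truth
  for (g in unique(tt$gene_id[tt$class == "partial_FNHG"]))
    expect_equal(sum(tt$trueDiff[tt$gene_id == g] == 0), 3)  # L=7: isoforms 5:7
  for (g in unique(tt$gene_id[tt$class == "full_FNHG"]))
    expect_equal(sum(tt$trueDiff[tt$gene_id == g] != 0), 7)
  # conservation: total DE isoforms
  expect_equal(sum(tt$isDE), 5 * 7 + 5 * 4)
  expect_error(simulateDataset(tpl, M = 10, m0 = 5, n = 5), "even")
})

test_that("the sample covariance converges to the generating matrix", {
  set.seed(34)
  tpl <- templateFixture(5)
  sim <- simulateDataset(tpl, M = 1, m0 = 1, n = 5000)
  g <- sim$genes[[1]]
  SigmaTrue <- buildCovariance(tpl@varReduced, "unequal_variance", 5)
  emp <- cov(t(g@Y[, conditions(g) == "c1"]))
  expect_lt(norm(emp - SigmaTrue, "F") / norm(SigmaTrue, "F"), 0.1)
})

test_that("generation is bit-reproducible under a fixed seed", {
  tpl <- templateFixture(5)
  set.seed(99); a <- simulateDataset(tpl, M = 6, m0 = 2, n = 10)
  set.seed(99); b <- simulateDataset(tpl, M = 6, m0 = 2, n = 10)
  expect_identical(lapply(a$genes, function(g) g@Y),
                   lapply(b$genes, function(g) g@Y))
  expect_identical(a$truth, b$truth)
})

test_that("replicate scoring matches a hand-counted 3-gene toy", {
  # gene A: NHG, discovered -> false discovery.
  # gene B: full FNHG (2 DE isoforms), discovered, rejects only isoform 1.
  # gene C: partial FNHG (iso1 DE, iso2 null), discovered, rejects both
  #         -> false discovery (null isoform rejected).
  truth <- data.frame(
    gene_id = rep(c("A", "B", "C"), each = 2),
    isoform_id = rep(c("i1", "i2"), 3),
    class = rep(c("NHG", "full_FNHG", "partial_FNHG"), each = 2),
    trueDiff = c(0, 0, 1, 1, 1, 0))
  truth$isDE <- truth$trueDiff != 0
  screening <- data.frame(gene_id = c("A", "B", "C"),
                          pvalue = c(0.001, 0.001, 0.001),
                          fdr = 0.001, passed = TRUE)
  conf <- data.frame(gene_id = rep(c("A", "B", "C"), each = 2),
                     isoform_id = rep(c("i1", "i2"), 3),
                     pvalue = 0.001, threshold = 0.01,
                     rejected = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE))
  res <- new("TwoStepResult", alpha = 0.05, M = 3L, R = 3L,
             fwerMethod = "hochberg", screenType = "type1",
             confirmatoryMethod = "wald", screening = screening,
             confirmatory = conf)
  met <- evaluateReplicate(list(truth = truth), res)
  expect_equal(met$R, 3)
  expect_equal(met$V, 2)                 # A (NHG) and C (null isoform hit)
  expect_equal(met$ofdr, 2 / 3)
  expect_equal(met$powerI, 2 / 3)        # rejected B:i1, C:i1 of 3 DE isoforms
  expect_equal(met$powerII, 0)           # B missed i2; C rejected a null
  # R = 0 contributes OFDR 0 by convention
  screening0 <- transform(screening, passed = FALSE)
  res0 <- new("TwoStepResult", alpha = 0.05, M = 3L, R = 0L,
              fwerMethod = "hochberg", screenType = "type1",
              confirmatoryMethod = "wald", screening = screening0,
              confirmatory = conf[0, ])
  expect_equal(evaluateReplicate(list(truth = truth), res0)$ofdr, 0)
})

test_that("the naive BH comparator matches a hand-run joint BH", {
  set.seed(35)
  tpl <- templateFixture(5)
  sim <- simulateDataset(tpl, M = 6, m0 = 2, n = 20)
  sb <- simpleBHComparator(sim$genes, alpha = 0.05)
  # oracle: Welch p per isoform, BH jointly
  p <- unlist(lapply(sim$genes, function(g) sapply(seq_len(5), function(l) {
    lev <- levels(g@condition)
    oracleWelch(g@Y[l, g@condition == lev[1]], g@Y[l, g@condition == lev[2]])$p
  })))
  rej <- oracleBH(p, 0.05)
  byGene <- matrix(rej, nrow = 5)
  expect_equal(sb@R, sum(colSums(byGene) > 0))
  expect_equal(unname(screening(sb)$passed), unname(colSums(byGene) > 0))
  cf <- confirmatory(sb)
  expect_equal(sum(cf$rejected), sum(rej))
  # every rejected isoform belongs to a discovered gene
  expect_true(all(cf$gene_id[cf$rejected] %in%
                    screening(sb)$gene_id[screening(sb)$passed]))
})

test_that("a small end-to-end study is deterministic and well-formed", {
  tpl <- templateFixture(5)
  cfg <- simulationConfig(M = 12, m0 = c(8, 12), n = 25, template = tpl,
                          replications = 2, seed = 7)
  s1 <- runSimulationStudy(cfg)
  s2 <- runSimulationStudy(cfg)
  expect_identical(s1@summary, s2@summary)
  expect_identical(s1@replicates, s2@replicates)
  expect_setequal(unique(s1@summary$method),
                  c("bonferroni", "holm", "hochberg", "simpleBH"))
  expect_setequal(unique(s1@summary$m0), c(8, 12))
  ok <- is.finite(as.matrix(s1@summary[, c("ofdr", "powerI", "powerII")]))
  vals <- as.matrix(s1@summary[, c("ofdr", "powerI", "powerII")])[ok]
  expect_true(all(vals >= 0 & vals <= 1))
  # m0 = M rows have no power denominators
  expect_true(all(is.na(s1@summary$powerII[s1@summary$m0 == 12])))
})
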