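test_that("nearest-gene lookup handles containment, ties and empty chromosomes", {
  genes <- GRanges(c("chr1", "chr1", "chr1", "chr2"),
                   IRanges(c(100, 900, 950, 10), c(500, 1200, 1300, 50)),
                   symbol = c("A", "B", "C", "D"))
  cpgs <- GRanges(c("chr1", "chr1", "chr1", "chr3"),
                  IRanges(c(200, 1000, 700, 5), width = 1))
  ann <- nearestGene(cpgs, genes)
  expect_identical(ann$symbols, c("A", "B;C", "A;B", NA))  # 700 ties A (199) / B (199)
  expect_identical(ann$distance, c(0, 0, 199, NA))
  # order of the gene list is irrelevant
  ann2 <- nearestGene(cpgs, rev(genes))
  expect_identical(ann, ann2)
})

test_that("gene models round-trip through BED and GFF3 with correct coordinates", {
  bed <- file.path(tempdir(), "genes.bed")
  # BED is 0-based half-open: this line is 1-based [101, 500]
  writeLines(c("chr1\t100\t500\tGENEA\t0\t+",
               "chr1\t899\t1200\tGENEB\t0\t-"), bed)
  gr <- readGeneModels(bed)
  expect_identical(start(gr), c(101L, 900L))
  expect_identical(end(gr), c(500L, 1200L))
  expect_identical(gr$symbol, c("GENEA", "GENEB"))

  gff <- file.path(tempdir(), "genes.gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "test", "gene", "101", "500", ".", "+", ".",
                     "ID=g1;Name=GENEA", sep = "\t"),
               paste("chr1", "test", "exon", "101", "200", ".", "+", ".",
                     "ID=e1;Parent=g1", sep = "\t")), gff)
  gg <- readGeneModels(gff)
  expect_length(gg, 1L)          # exon records are dropped
  expect_identical(start(gg), 101L)
  expect_identical(gg$symbol, "GENEA")
})

test_that("EWAS rows pick up their gene annotation", {
  rows <- probeRows(c(150L, 2000L), c(1e-5, 0.2))
  rows$gene_symbols <- NA_character_
  genes <- GRanges("chr1", IRanges(100, 300), symbol = "NEAR")
  out <- annotateNearestGene(rows, genes)
  expect_identical(out$gene_symbols, c("NEAR", "NEAR"))
  expect_identical(out$gene_distance, c(0, 1699))
})

test_that("rank-sum p-values match exhaustive enumeration", {
  expect_equal(wilcoxonCaseControl(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(wilcoxonCaseControl(c(5, 5, 5), c(5, 5, 5)), 1)
  # enumeration oracle: all C(n1+n2, n1) assignments of the pooled values
  enumP <- function(x, y) {
    pooled <- c(x, y); n1 <- length(x)
    W <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
    Ws <- combn(length(pooled), n1, function(i)
      sum(rank(pooled)[i]) - n1 * (n1 + 1) / 2)
    mean(abs(Ws - n1 * length(y) / 2) >= abs(W - n1 * length(y) / 2))
  }
  set.seed(44)
  for (r in 1:5) {
    x <- sample(seq(1, 97, 3), 4)     # tie-free by construction
    y <- sample(seq(2, 98, 3), 5)
    expect_equal(wilcoxonCaseControl(x, y), enumP(x, y), tolerance = 1e-12)
  }
  # rank statistic: invariant to strictly monotone transforms
  x <- c(0.1, 0.4, 0.9, 0.2); y <- c(0.5, 0.3, 0.8)
  expect_equal(wilcoxonCaseControl(x, y), wilcoxonCaseControl(exp(x), exp(y)))
  expect_error(wilcoxonCaseControl(numeric(0), 1), "at least one")
})

test_that("logistic validation recovers a known log odds ratio", {
  set.seed(45)
  est <- replicate(50, {
    meth <- rnorm(500, 0.5, 0.15)
    pr <- plogis(-0.5 + 1.0 * meth)
    status <- rbinom(500, 1, pr)
    logisticAssoc(meth, status)$beta
  })
  expect_lt(abs(median(est) - 1.0), 0.3)
})

test_that("logistic null estimates are calibrated", {
  set.seed(46)
  cover <- replicate(100, {
    meth <- rnorm(300, 0.5, 0.1)
    status <- rbinom(300, 1, 0.4)
    fit <- logisticAssoc(meth, status)
    abs(fit$beta) <= 2 * fit$se
  })
  expect_gte(sum(cover), 93)
})

test_that("degenerate logistic designs are handled explicitly", {
  set.seed(47)
  meth <- rnorm(80); status <- rbinom(80, 1, 0.5)
  expect_warning(
    out <- logisticAssoc(meth, status, covariates = data.frame(bmi = rep(24, 80))),
    "constant")
  expect_identical(out$flag, "ok")
  # perfect separation flagged, no estimate
  sep <- logisticAssoc(c(1:10, 21:30), rep(c(0, 1), each = 10))
  expect_identical(sep$flag, "separation")
  expect_true(is.na(sep$beta))
  expect_error(logisticAssoc(meth, rep(1, 80)), "both outcome classes")
})

test_that("candidate validation table is coherent", {
  se <- simulateTwinCohort(simScenario("null", n_pairs = 60, n_cpgs = 6, seed = 55))
  cd <- cohortData(se)
  b <- betaValues(se)
  val <- validateCpgs(b, cd$case_status, cd[, c("bmi", "tg", "fbg")])
  expect_identical(nrow(val), 6L)
  expect_true(all(val$wilcoxon_p > 0 & val$wilcoxon_p <= 1))
  md <- apply(b, 1, function(v)
    median(v[cd$case_status]) - median(v[!cd$case_status]))
  expect_identical(val$direction, unname(ifelse(md > 0, "hyper", "hypo")))
})

test_that("intra-pair partial correlation equals its residualization oracle", {
  se <- simPrepped(name = "meth_causal", n_pairs = 60, n_cpgs = 20,
                   n_signal_cpgs = 2, seed = 66)
  cd <- cohortData(se)
  keep <- !is.na(cd$sbp_derived)
  sig <- which(truthData(se)$is_signal)[1]
  r <- intrapairPartialCorrelation(se[, keep], "SBP", cpgs = sig)
  # oracle: explicit per-pair differences, lm residuals, Pearson correlation
  cdk <- cohortData(se[, keep]); Mk <- mValues(se[, keep])
  i1 <- which(cdk$twin_index == 1L)
  i2 <- match(cdk$pair_id[i1], cdk$pair_id[which(cdk$twin_index == 2L)])
  i2 <- which(cdk$twin_index == 2L)[i2]
  dbp <- cdk$sbp_derived[i1] - cdk$sbp_derived[i2]
  dm <- Mk[sig, i1] - Mk[sig, i2]
  Z <- cbind(age = cdk$age_years[i1], sex = as.numeric(cdk$sex[i1] == "M"))
  want <- cor(resid(lm(dbp ~ Z)), resid(lm(dm ~ Z)))
  expect_equal(unname(r), want, tolerance = 1e-12)
  # no covariates: plain Pearson correlation of the differences
  r0 <- intrapairPartialCorrelation(se[, keep], "SBP", cpgs = sig,
                                    covariates = character(0))
  expect_equal(unname(r0), cor(dbp, dm), tolerance = 1e-12)
})

test_that("partial correlation is invariant when both twin orderings flip", {
  se <- simPrepped(name = "meth_causal", n_pairs = 50, n_cpgs = 20,
                   n_signal_cpgs = 2, seed = 67)
  keep <- !is.na(cohortData(se)$sbp_derived)
  se <- se[, keep]
  sig <- which(truthData(se)$is_signal)[1]
  r <- intrapairPartialCorrelation(se, "SBP", cpgs = sig)
  # swapping twin labels flips both difference vectors: correlation unchanged
  cd2 <- cohortData(se); cd2$twin_index <- 3L - cd2$twin_index
  se2 <- se
  SummarizedExperiment::colData(se2) <-
    S4Vectors::DataFrame(cd2, row.names = cd2$individual_id)
  expect_equal(intrapairPartialCorrelation(se2, "SBP", cpgs = sig), r,
               tolerance = 1e-12)
})

test_that("partial correlation recovers the generator's target", {
  # analytic target for this scenario (2 signal CpGs, effect 15, rho 0.6,
  # BP noise 16): r = 0.27; Monte-Carlo sd at 200 pairs is about 0.07
  rs <- vapply(1:3, function(s) {
    se <- simPrepped(name = "meth_causal", n_pairs = 200, n_cpgs = 40,
                     n_signal_cpgs = 2, seed = 400 + s)
    keep <- !is.na(cohortData(se)$sbp_derived)
    sig <- which(truthData(se)$is_signal)[1]
    unname(intrapairPartialCorrelation(se[, keep], "SBP", cpgs = sig))
  }, numeric(1))
  expect_lt(abs(median(rs) - 0.27), 0.1)
  tiny <- simPrepped(name = "null", n_pairs = 3, n_cpgs = 5, seed = 1)
  expect_error(intrapairPartialCorrelation(tiny, "SBP", cpgs = 1), "4 complete")
})
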