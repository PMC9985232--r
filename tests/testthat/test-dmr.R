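test_that("autocorrelation of independent p-values is near zero in every bin", {
  set.seed(30)
  pos <- sort(sample.int(6e5, 5000))
  acf <- estimateAcf(probeRows(pos, runif(5000)), max_dist = 500, bin_size = 50)
  expect_length(acf$correlations, 10L)
  expect_true(all(abs(acf$correlations) <= 0.05))
})

test_that("duplicated signals at short range give first-bin correlation near one", {
  set.seed(31)
  base <- sort(sample.int(1e6, 400))
  base <- base[diff(c(0, base)) > 600]        # isolate the pairs
  p <- runif(length(base))
  pos <- c(base, base + 10L)
  acf <- estimateAcf(probeRows(pos, c(p, p)), max_dist = 500, bin_size = 50)
  expect_gte(acf$correlations[1], 0.99)
})

test_that("every probe pair lands in exactly one bin", {
  set.seed(32)
  pos <- sort(sample(1:3000, 60))
  pos <- pos[diff(c(-10, pos)) > 0]
  acf <- estimateAcf(probeRows(pos, runif(length(pos))), max_dist = 300,
                     bin_size = 100)
  # brute-force pair census
  d <- as.vector(dist(pos))
  want <- table(cut(d[d <= 300], breaks = c(0, 100, 200, 300)))
  expect_identical(unname(acf$n_pairs), as.integer(want))
  expect_error(estimateAcf(probeRows(pos, runif(length(pos))), 10, 50), "max_dist")
})

test_that("Stouffer-Liptak adjustment has its closed-form limits", {
  # lone probe: untouched
  rows <- probeRows(c(1000L, 50000L), c(0.02, 0.6))
  acf <- estimateAcf(probeRows(sort(sample.int(1e5, 200)), runif(200)))
  adj <- slkAdjust(rows, acf, window = 200)
  expect_equal(adj, c(0.02, 0.6), tolerance = 1e-12)

  # two perfectly correlated probes with equal z keep their p
  acf1 <- structure(list(bin_edges = seq(0, 500, 50), correlations = rep(1, 10),
                         n_pairs = rep(10L, 10), bin_size = 50, max_dist = 500),
                    class = "AcfEstimate")
  rows2 <- probeRows(c(1000L, 1010L), c(0.07, 0.07))
  expect_equal(slkAdjust(rows2, acf1, 200), c(0.07, 0.07), tolerance = 1e-10)

  # independent probes with z = 1.5 combine to 1 - pnorm(2 * 1.5 / sqrt(2))
  acf0 <- structure(list(bin_edges = seq(0, 500, 50), correlations = rep(0, 10),
                         n_pairs = rep(10L, 10), bin_size = 50, max_dist = 500),
                    class = "AcfEstimate")
  p15 <- 1 - pnorm(1.5)
  rows3 <- probeRows(c(1000L, 1010L), c(p15, p15))
  expect_equal(slkAdjust(rows3, acf0, 200),
               rep(1 - pnorm(3 / sqrt(2)), 2), tolerance = 1e-10)
})

test_that("with zero correlation the window combination is classic Stouffer", {
  set.seed(33)
  acf0 <- structure(list(bin_edges = seq(0, 500, 50), correlations = rep(0, 10),
                         n_pairs = rep(10L, 10), bin_size = 50, max_dist = 500),
                    class = "AcfEstimate")
  pos <- c(100L, 150L, 220L, 290L)
  p <- runif(4)
  adj <- slkAdjust(probeRows(pos, p), acf0, window = 200)
  z <- qnorm(1 - p)
  expect_equal(adj[2], 1 - pnorm(sum(z) / 2), tolerance = 1e-10)  # sees all 4
})

test_that("region finding follows the gap rule and drops singletons", {
  rows <- probeRows(c(100L, 150L, 900L), rep(0.001, 3))
  reg <- findRegions(rows, c(0.001, 0.001, 0.001), seed_p = 0.01, max_gap = 200)
  expect_length(reg, 1L)
  expect_identical(c(start(reg), end(reg)), c(100L, 150L))
  expect_identical(reg$n_probes, 2L)
  # nothing below seed: empty
  expect_length(findRegions(rows, rep(0.5, 3), seed_p = 0.01, max_gap = 200), 0L)
})

test_that("region finding matches a brute-force scan on random inputs", {
  bruteRegions <- function(pos, adj, seed_p, max_gap) {
    sel <- which(adj < seed_p)
    out <- list(); cur <- integer(0)
    for (i in sel) {
      if (length(cur) && pos[i] - pos[cur[length(cur)]] <= max_gap)
        cur <- c(cur, i)
      else {
        if (length(cur) >= 2) out[[length(out) + 1]] <- range(pos[cur])
        cur <- i
      }
    }
    if (length(cur) >= 2) out[[length(out) + 1]] <- range(pos[cur])
    out
  }
  set.seed(34)
  for (r in 1:30) {
    n <- sample(10:80, 1)
    pos <- sort(sample.int(5000, n))
    adj <- runif(n)^2
    reg <- findRegions(probeRows(pos, adj), adj, seed_p = 0.2, max_gap = 150)
    want <- bruteRegions(pos, adj, 0.2, 150)
    expect_identical(length(reg), length(want))
    if (length(want))
      expect_identical(cbind(start(reg), end(reg)),
                       matrix(unlist(want), ncol = 2, byrow = TRUE))
  }
})

test_that("region scores have their fixed points and ordering", {
  pos <- c(100L, 140L, 180L)
  rows <- probeRows(c(pos, 5000L), c(0.5, 0.5, 0.5, 0.9))
  acf <- structure(list(bin_edges = seq(0, 500, 50),
                        correlations = c(0.4, rep(0.1, 9)),
                        n_pairs = rep(5L, 10), bin_size = 50, max_dist = 500),
                   class = "AcfEstimate")
  reg <- findRegions(rows, c(0.6, 0.6, 0.6, 1), seed_p = 0.7, max_gap = 100)
  sc <- scoreRegions(reg, rows, acf)
  expect_equal(sc$slk_p, 0.5, tolerance = 1e-12)   # all-z-zero fixed point
  expect_gte(sc$sidak_p, sc$slk_p)
  bad <- reg; bad$n_probes <- 1L
  expect_error(scoreRegions(bad, rows, acf), ">= 2")
})

test_that("distant p = 1 probes do not perturb region calls", {
  set.seed(35)
  pos <- sort(sample.int(2e5, 300))
  p <- runif(300)
  hotpos <- 60000L + cumsum(rep(40L, 6))          # a genuine region
  allpos <- c(pos, hotpos); allp <- c(p, rep(1e-6, 6))
  o <- order(allpos)
  rows <- probeRows(allpos[o], allp[o])
  d1 <- callDmrs(rows)
  extra <- probeRows(c(150000L, 180000L), c(1, 1))
  rows2 <- sort(c(rows, extra))
  d2 <- callDmrs(rows2)
  expect_identical(as.data.frame(d1)[, c("start", "end", "n_probes")],
                   as.data.frame(d2)[, c("start", "end", "n_probes")])
})

test_that("two implants far apart are called as two disjoint regions", {
  set.seed(36)
  se <- simulateTwinCohort(simScenario("null", n_pairs = 60, n_cpgs = 250, seed = 77))
  se <- implantDmr(se, "chr1", 40000L, 8L, 30L, effect = 1)
  se <- implantDmr(se, "chr1", 52000L, 8L, 30L, effect = 1)   # 10 kb away
  se <- suppressMessages(deriveBP(se, "SBP")); se <- betaToM(se)
  rows <- suppressMessages(runEwas(se, "SBP"))
  d <- callDmrs(rows)
  sig <- d[d$significant]
  expect_true(recovers(sig, 40000, 40210))
  expect_true(recovers(sig, 52000, 52210))
  # no called region spans both implants
  expect_false(any(start(sig) < 41000 & end(sig) > 51000))
})
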