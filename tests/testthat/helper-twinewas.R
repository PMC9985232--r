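# Shared fixtures for the suite: everything is generated in code.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# simulate, derive BP and transform in one call
simPrepped <- function(..., trait = "SBP") {
  se <- simulateTwinCohort(simScenario(...))
  se <- suppressMessages(deriveBP(se, trait))
  betaToM(se)
}

# tiny hand-built cohort with explicit readings
makeCohort <- function(sbp_by_pair) {
  P <- length(sbp_by_pair)
  n <- 2L * P
  sbp <- unlist(sbp_by_pair)
  data.frame(
    individual_id = sprintf("i%02d", seq_len(n)),
    pair_id = rep(sprintf("p%02d", seq_len(P)), each = 2L),
    twin_index = rep(1:2, P),
    sex = rep("F", n), age_years = rep(50, n),
    sbp1 = sbp, sbp2 = sbp, sbp3 = sbp,
    stringsAsFactors = FALSE)
}

# GRanges of 1bp probes with p-values, for the DMR machinery
probeRows <- function(pos, p, chrom = "chr1") {
  GRanges(chrom, IRanges(pos, width = 1), p_value = p)
}

# reciprocal-overlap test between one truth interval and called regions
recovers <- function(regions, t_start, t_end, min_ro = 0.5) {
  if (!length(regions)) return(FALSE)
  ov <- pmin(end(regions), t_end) - pmax(start(regions), t_start) + 1
  w <- pmax(end(regions) - start(regions) + 1, t_end - t_start + 1)
  any(ov > 0 & ov / w >= min_ro)
}

# ICE FALCON fit of one CpG of a prepared experiment
iceFitCpg <- function(se, cpg_idx, direction, n_boot = 300, seed = 1, ...) {
  cd <- cohortData(se)
  m <- mValues(se)[cpg_idx, ]
  bp <- cd$sbp_derived
  keep <- !(cd$pair_id %in% cd$pair_id[is.na(m) | is.na(bp)])
  tb <- if (direction == "meth_to_bp")
    reshapePairs(cd[keep, ], x = m[keep], y = bp[keep])
  else reshapePairs(cd[keep, ], x = bp[keep], y = m[keep])
  iceFalconFit(tb, direction, n_boot = n_boot, seed = seed, ...)
}

# brute-force BH step-up, independent of p.adjust
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o[m]] <- p[o[m]]
  for (i in (m - 1):1) if (m > 1)
    q[o[i]] <- min(p[o[i]] * m / i, q[o[i + 1]])
  pmin(q, 1)
}
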