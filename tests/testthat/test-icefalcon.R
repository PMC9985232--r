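test_that("pair-long reshaping has the documented geometry", {
  se <- simPrepped(name = "null", n_pairs = 60, n_cpgs = 5, seed = 2)
  cd <- cohortData(se)
  tb <- reshapePairs(cd, x = mValues(se)[1, ], y = cd$sbp_derived)
  expect_identical(nrow(tb), 120L)
  expect_identical(anyDuplicated(tb$self_id), 0L)
  # the co-twin column is the self column under the within-pair index swap
  swap <- unlist(lapply(split(seq_len(nrow(tb)), tb$pair_id), rev),
                 use.names = FALSE)
  expect_identical(tb$x_cotwin, tb$x_self[swap])
  # incomplete pairs are refused by name
  x <- mValues(se)[1, ]; x[1] <- NA
  expect_error(reshapePairs(cd, x, cd$sbp_derived), cd$pair_id[1])
})

test_that("swapping twin labels leaves the fit unchanged", {
  se <- simPrepped(name = "meth_causal", n_pairs = 40, n_cpgs = 20,
                   n_signal_cpgs = 2, seed = 8)
  cd <- cohortData(se)
  m <- mValues(se)[which(truthData(se)$is_signal)[1], ]
  tb <- reshapePairs(cd, m, cd$sbp_derived)
  cd2 <- cd
  cd2$twin_index <- 3L - cd2$twin_index
  o <- order(cd2$pair_id, cd2$twin_index)
  tb2 <- reshapePairs(cd2[o, ], m[o], cd$sbp_derived[o])
  f1 <- iceFalconFit(tb, "meth_to_bp", n_boot = 50, seed = 4)
  f2 <- iceFalconFit(tb2, "meth_to_bp", n_boot = 50, seed = 4)
  expect_equal(f1$beta_self, f2$beta_self, tolerance = 1e-10)
  expect_equal(f1$beta_cotwin_full, f2$beta_cotwin_full, tolerance = 1e-10)
})

test_that("verdict rules reproduce the published decision pattern", {
  fit <- list(p_cotwin_change = 0.046, ratio_raw = 4.483)
  expect_identical(classifyCausality(fit), "causal")
  fit$p_cotwin_change <- 0.198
  expect_identical(classifyCausality(fit), "inconclusive")
  expect_identical(classifyCausality(list(p_cotwin_change = 0.01,
                                          ratio_raw = 1.2)),
                   "familial_confounding")
  expect_identical(classifyCausality(list(p_cotwin_change = NA_real_,
                                          ratio_raw = 2)), "inconclusive")
})

test_that("the stored ratio is recomputable from the four coefficients", {
  se <- simPrepped(name = "meth_causal", n_pairs = 50, n_cpgs = 20,
                   n_signal_cpgs = 2, seed = 9)
  f <- iceFitCpg(se, which(truthData(se)$is_signal)[1], "meth_to_bp",
                 n_boot = 100, seed = 3)
  expect_equal(f$self_change, f$beta_self - f$beta_self_full, tolerance = 1e-12)
  expect_equal(f$cotwin_change, f$beta_cotwin - f$beta_cotwin_full,
               tolerance = 1e-12)
  expect_equal(f$ratio_raw, abs(f$cotwin_change) / abs(f$self_change),
               tolerance = 1e-12)
  expect_gte(f$ratio_raw, 0)
})

test_that("verdicts are invariant under affine rescaling of both variables", {
  se <- simPrepped(name = "meth_causal", n_pairs = 60, n_cpgs = 20,
                   n_signal_cpgs = 2, seed = 14)
  cd <- cohortData(se)
  m <- mValues(se)[which(truthData(se)$is_signal)[1], ]
  y <- cd$sbp_derived
  keep <- !(cd$pair_id %in% cd$pair_id[is.na(y)])
  f1 <- iceFalconFit(reshapePairs(cd[keep, ], m[keep], y[keep]),
                     "meth_to_bp", n_boot = 200, seed = 6)
  f2 <- iceFalconFit(reshapePairs(cd[keep, ], 3 * m[keep] + 2,
                                  0.5 * y[keep] - 40),
                     "meth_to_bp", n_boot = 200, seed = 6)
  expect_equal(f1$ratio_raw, f2$ratio_raw, tolerance = 1e-8)
  expect_identical(f1$verdict, f2$verdict)
})

test_that("bidirectional runs are deterministic and complete", {
  se <- simPrepped(name = "meth_causal", n_pairs = 40, n_cpgs = 40,
                   n_signal_cpgs = 2, seed = 22)
  rows <- suppressMessages(runEwas(se, "SBP"))
  top <- topCpgs(rows, 1e-3)
  expect_gte(length(top), 1L)
  a <- runIceFalcon(se, "SBP", top, n_boot = 100, seed = 5)
  b <- runIceFalcon(se, "SBP", top, n_boot = 100, seed = 5)
  expect_identical(a, b)
  expect_identical(nrow(a), 2L * length(top))
  expect_setequal(unique(a$direction), c("meth_to_bp", "bp_to_meth"))
})

test_that("a strong methylation-causal signal earns a causal verdict", {
  se <- simPrepped(name = "meth_causal", n_pairs = 100, n_cpgs = 40,
                   n_signal_cpgs = 2, seed = 103)
  f <- iceFitCpg(se, which(truthData(se)$is_signal)[1], "meth_to_bp",
                 n_boot = 400, seed = 1)
  expect_identical(f$verdict, "causal")
  expect_gt(f$ratio, 1.5)
  expect_lt(f$p_cotwin_change, 0.05)
})

test_that("reverse causation is detected in the reverse orientation more often", {
  cnt <- c(meth_to_bp = 0L, bp_to_meth = 0L)
  for (s in 1:10) {
    se <- simPrepped(name = "bp_causal", n_pairs = 150, n_cpgs = 30,
                     n_signal_cpgs = 2, intra_pair_rho = 0.1,
                     familial_load_bp = 12, causal_effect = 0.03,
                     seed = 300 + s)
    sig <- which(truthData(se)$is_signal)[1]
    for (dir in names(cnt)) {
      f <- iceFitCpg(se, sig, dir, n_boot = 300, seed = 1)
      cnt[dir] <- cnt[dir] + (f$verdict == "causal")
    }
  }
  expect_gt(cnt[["bp_to_meth"]], cnt[["meth_to_bp"]])
})

test_that("null data rarely produce causal verdicts", {
  causal <- 0L
  for (s in 1:8) {
    se <- simPrepped(name = "null", n_pairs = 60, n_cpgs = 10, seed = 500 + s)
    for (dir in c("meth_to_bp", "bp_to_meth")) {
      f <- iceFitCpg(se, 1L, dir, n_boot = 200, seed = 2)
      causal <- causal + (f$verdict == "causal")
    }
  }
  expect_lte(causal, 2L)   # 16 fits, nominal rate would be well under 10%
})
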