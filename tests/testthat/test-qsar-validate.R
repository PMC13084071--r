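test_that("internal metrics match the brute-force LOO oracle", {
  ## tiny hand case: single descriptor
  d <- qsarDataset(matrix(c(1, 2, 3, 5), ncol = 1,
                          dimnames = list(NULL, "x")),
                   y = c(1, 2, 3, 4))
  m <- fitMlr(d, "x")
  rep <- internalMetrics(m, d)
  expect_equal(rep@internal[["press"]], 1.435938527285,
               tolerance = 1e-10)

  ## property: leverage shortcut equals explicit n-refit LOO (n <= 30)
  for (seed in 1:5) {
    gen <- makePlanted(n = 10 + 4 * seed, m = 4, k = 2, noiseSd = 0.3,
                       seed = seed)
    d <- gen$dataset
    m <- fitMlr(d, descriptorNames(d))
    rep <- internalMetrics(m, d)
    bf <- bruteForcePress(descriptorMatrix(d), activity(d))
    expect_equal(rep@internal[["press"]], bf, tolerance = 1e-8)
  }
})

test_that("perfect fits score perfectly everywhere", {
  gen <- makePlanted(n = 40, m = 4, k = 4, noiseSd = 0, seed = 2)
  d <- gen$dataset
  m <- fitMlr(d, descriptorNames(d))
  rep <- internalMetrics(m, d)
  expect_equal(rep@internal[["r2"]], 1, tolerance = 1e-10)
  expect_equal(rep@internal[["q2_loo"]], 1, tolerance = 1e-10)
  expect_equal(rep@internal[["see"]], 0, tolerance = 1e-7)
  expect_equal(rep@internal[["press"]], 0, tolerance = 1e-12)

  ext <- externalMetrics(m, d)
  expect_equal(ext@external[["r2"]], 1, tolerance = 1e-10)
  expect_equal(ext@external[["q2_f1"]], 1, tolerance = 1e-10)
  expect_equal(ext@external[["q2_f2"]], 1, tolerance = 1e-10)
  expect_equal(ext@external[["rmsep"]], 0, tolerance = 1e-7)
  expect_equal(ext@external[["mae_95"]], 0, tolerance = 1e-7)
  expect_identical(ext@maeVerdict, "GOOD")
  ro <- regressionThroughOrigin(activity(d),
                                applyModel(m, d,
                                           warnExtrapolation = FALSE))
  expect_equal(unname(ro), c(1, 1, 1, 1), tolerance = 1e-10)
  rm2 <- rm2Metrics(activity(d),
                    applyModel(m, d, warnExtrapolation = FALSE))
  expect_equal(rm2[["avg_rm2"]], 1, tolerance = 1e-8)
  expect_equal(rm2[["delta_rm2"]], 0, tolerance = 1e-8)
})

test_that("through-origin metrics match the formula oracle", {
  ## frozen values from the independent direct-formula transcription
  ro <- regressionThroughOrigin(c(1, 2, 3), c(1.1, 1.9, 3.2))
  expect_equal(ro[["r0_2"]], 0.990731436273, tolerance = 1e-10)
  expect_equal(ro[["r0_prime_2"]], 0.991071428571, tolerance = 1e-10)
  expect_equal(ro[["k"]], 0.962815405046, tolerance = 1e-10)
  expect_equal(ro[["k_prime"]], 1.035714285714, tolerance = 1e-10)

  ## scaling: y_pred = 2 y_obs halves k and doubles k'
  yo <- c(1, 2, 3, 4)
  ro2 <- regressionThroughOrigin(yo, 2 * yo)
  expect_equal(ro2[["k"]], 0.5)
  expect_equal(ro2[["k_prime"]], 2)

  ## property over random cases: package agrees with the oracle
  for (seed in 1:10) {
    yo <- withr::with_seed(seed, rnorm(8, 6))
    yp <- withr::with_seed(seed + 100, yo + rnorm(8, 0, 0.4))
    expect_equal(regressionThroughOrigin(yo, yp),
                 oracleThroughOrigin(yo, yp), tolerance = 1e-12)
  }
  expect_error(regressionThroughOrigin(c(1, 1, 1), c(1, 2, 3)),
               "variance")
})

test_that("rm2 metrics follow the radical form with clamping", {
  yo <- c(5, 6, 7, 8); yp <- c(5.2, 5.9, 7.3, 7.8)
  rm2 <- rm2Metrics(yo, yp)
  ## both radicands are negative here (r0^2 > r2): clamped to rm2 = r2
  expect_true(attr(rm2, "clamped"))
  expect_equal(rm2[["rm2"]], 0.968421052632, tolerance = 1e-10)
  expect_equal(rm2[["delta_rm2"]], 0, tolerance = 1e-10)

  ## unclamped case (systematically offset predictions): direct
  ## evaluation of the radical formula, which may go negative
  yo <- c(5, 6, 7, 8); yp <- yo + 1.5 + c(0.1, -0.1, 0.05, -0.05)
  r2 <- cor(yo, yp)^2
  ro <- oracleThroughOrigin(yo, yp)
  exp_rm2 <- r2 * (1 - sqrt(max(0, r2 - ro[["r0_2"]])))
  got <- rm2Metrics(yo, yp)
  expect_false(attr(got, "clamped"))
  expect_equal(got[["rm2"]], exp_rm2, tolerance = 1e-12)
  expect_lt(got[["rm2"]], 0)  # preserved, not clamped to [0, 1]

  ## the scaling flag changes the result for imperfect predictions
  expect_false(isTRUE(all.equal(rm2Metrics(yo, yp, scale = TRUE)[["rm2"]],
                                got[["rm2"]])))
  ## ... but not for perfect ones
  expect_equal(rm2Metrics(yo, yo, scale = TRUE)[["rm2"]], 1)
})

test_that("external metrics trim the worst 5% for the MAE judgement", {
  gen <- makePlanted(n = 60, m = 4, k = 2, noiseSd = 0.2, seed = 41)
  d <- gen$dataset
  m <- fitMlr(d[1:40, ], descriptorNames(d)[1:3])
  test <- d[41:60, ]
  ## plant one gross outlier in the test activities
  yOut <- activity(test); yOut[5] <- yOut[5] + 50
  testOut <- qsarDataset(descriptorMatrix(test), yOut,
                         compounds = compoundIds(test))
  rep <- externalMetrics(m, testOut)
  ## brute-force sort-and-trim oracle
  err <- abs(applyModel(m, testOut, warnExtrapolation = FALSE,
                        warnExtra = FALSE) - yOut)
  kept <- sort(err)[seq_len(20 - ceiling(0.05 * 20))]
  expect_equal(rep@external[["mae_95"]], mean(kept), tolerance = 1e-12)
  expect_equal(rep@external[["sd_95"]], sd(kept), tolerance = 1e-12)
  ## the planted outlier is the dropped error
  expect_lt(rep@external[["mae_95"]], mean(err))

  expect_warning(externalMetrics(m, testOut[1:2, ]), "unreliable")
})

test_that("Golbraikh-Tropsha checker applies the published thresholds", {
  vals <- list(q2 = 0.873, r2 = 0.867, r0_2 = 0.862,
               r0_prime_2 = 0.814, k = 1.001, k_prime = 0.998)
  chk <- golbraikhTropshaCheck(vals)
  expect_equal(nrow(chk), 5L)
  expect_true(all(chk$passed))
  det <- attr(chk, "details")
  expect_equal(round(det[["ratio_r2_r02"]], 3), 0.006)

  ## slope out of band fails the unprimed branch but k' can rescue it
  vals$k <- 1.2
  expect_true(golbraikhTropshaCheck(vals)$passed[3])  # primed branch
  vals$k_prime <- 1.2
  expect_false(golbraikhTropshaCheck(vals)$passed[3])

  ## criterion IV threshold
  vals2 <- list(q2 = 0.9, r2 = 0.9, r0_2 = 0.9, r0_prime_2 = 0.59,
                k = 1, k_prime = 1)
  expect_false(golbraikhTropshaCheck(vals2)$passed[4])

  expect_error(golbraikhTropshaCheck(list(q2 = 0.9)), "missing field")
})

test_that("applicability domain follows the hat-matrix identities", {
  gen <- makePlanted(n = 50, m = 8, k = 3, noiseSd = 0.2, seed = 19)
  d <- gen$dataset
  m <- fitMlr(d, descriptorNames(d), autoscale = TRUE)
  ad <- applicabilityDomain(m, d)
  tab <- ad@table
  ## trace(H) = p; all leverages in [1/n-ish, 1]
  expect_equal(sum(tab$leverage), 9, tolerance = 1e-10)
  expect_true(all(tab$leverage >= 0 & tab$leverage <= 1))
  expect_equal(ad@hStar, 3 * 9 / 50)
  ## a query at the training centroid has minimal leverage 1/n
  centroid <- colMeans(descriptorMatrix(d))
  q <- qsarDataset(matrix(centroid, nrow = 1,
                          dimnames = list(NULL, names(centroid))),
                   y = mean(activity(d)), compounds = "centroid")
  adq <- applicabilityDomain(m, d, q)
  expect_equal(adq@table$leverage[adq@table$set == "query"], 1 / 50,
               tolerance = 1e-10)
  ## in-domain flag is exactly the conjunction of the two bounds
  expect_identical(tab$inDomain,
                   tab$leverage <= ad@hStar & abs(tab$stdResidual) <= 3)
})

test_that("Williams table exports with the documented columns", {
  gen <- makePlanted(n = 30, m = 4, k = 2, noiseSd = 0.2, seed = 3)
  m <- fitMlr(gen$dataset, descriptorNames(gen$dataset))
  ad <- applicabilityDomain(m, gen$dataset)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeWilliamsTsv(ad, tf)
  back <- read.delim(tf)
  expect_identical(names(back), c("id", "leverage", "std_residual",
                                  "set", "in_domain"))
  expect_equal(nrow(back), 30L)
})
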