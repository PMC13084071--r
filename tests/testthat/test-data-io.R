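test_that("readQsarCsv parses a descriptor table and enforces contracts", {
  tf <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("a", "b", "c"), D1 = c(0.1, 0.2, 0.3),
                       D2 = c(1, 2, 3), pIC50 = c(5, 6, 7)),
            tf, row.names = FALSE)
  d <- readQsarCsv(tf, "pIC50")
  expect_s4_class(d, "QsarDataset")
  expect_equal(dim(d), c(3L, 2L))
  expect_identical(descriptorNames(d), c("D1", "D2"))
  expect_equal(activity(d), c(5, 6, 7))

  expect_error(readQsarCsv(tf, "missing_col"), "activity column")

  write.csv(data.frame(id = c("a", "a"), D1 = 1:2, pIC50 = c(5, 6)),
            tf, row.names = FALSE)
  expect_error(readQsarCsv(tf, "pIC50"), "duplicate")
})

test_that("CSV round-trip preserves descriptor values at full precision", {
  gen <- makePlanted(n = 12, m = 4, seed = 3, noiseSd = 0.1)
  tf <- withr::local_tempfile(fileext = ".csv")
  writeQsarCsv(gen$dataset, tf)
  back <- readQsarCsv(tf)
  expect_equal(descriptorMatrix(back), descriptorMatrix(gen$dataset),
               tolerance = 1e-12)
  expect_equal(activity(back), activity(gen$dataset), tolerance = 1e-12)
})

test_that("typographic minus and spread notation are parsed", {
  p <- parseSpread(c("−44.05 ± 7.74", "1.5", "2 +/- 0.1"))
  expect_equal(p$value, c(-44.05, 1.5, 2))
  expect_equal(p$spread, c(7.74, NA, 0.1))
})

test_that("model JSON round-trips field-for-field", {
  m <- publishedModel("PTP1B")
  tf <- withr::local_tempfile(fileext = ".json")
  writeModelJson(m, tf)
  back <- readModelJson(tf)
  expect_equal(back@intercept, 6.697)
  expect_equal(back@coefficients, m@coefficients)
  expect_equal(back@coefSE, m@coefSE)
  expect_equal(length(back@coefficients), 8L)

  gen <- makePlanted(n = 30, m = 5, k = 2, noiseSd = 0.1)
  m2 <- fitMlr(gen$dataset, descriptorNames(gen$dataset)[1:3],
               autoscale = TRUE)
  writeModelJson(m2, tf)
  back2 <- readModelJson(tf)
  expect_equal(back2@coefficients, m2@coefficients, tolerance = 1e-14)
  expect_equal(back2@scaling$center, m2@scaling$center,
               tolerance = 1e-14)
  expect_equal(back2@training$yRange, m2@training$yRange,
               tolerance = 1e-14)
})

test_that("invalid models are rejected at construction", {
  expect_error(new("MlrModel", intercept = 1, interceptSE = 0,
                   coefficients = numeric(), coefSE = numeric(),
                   scaling = list(), training = list()),
               "at least one descriptor")
  ## scaling covering only part of the descriptors violates the contract
  expect_error(new("MlrModel", intercept = 1, interceptSE = 0,
                   coefficients = c(a = 1, b = 2),
                   coefSE = c(a = 0.1, b = 0.1),
                   scaling = list(center = c(a = 0), scale = c(a = 1)),
                   training = list()),
               "cover every model descriptor")
})

test_that("fixtures load with printed values, types and flags", {
  expect_error(loadFixture("nope"), "available")

  t2 <- suppressWarnings(loadFixture("table2"))
  expect_equal(nrow(t2), 12L)
  expect_equal(t2$g_bind[t2$complex == "PTP1B-Q37DG"], -52.19)
  expect_equal(t2$g_bind_spread[t2$complex == "PTP1B-Q37DG"], 8.31)
  ## the two internally inconsistent printed rows are flagged, not fixed
  expect_identical(t2$complex[t2$flagInconsistent],
                   c("PTP1B-Q7G", "DPP4-Q7G"))
  expect_warning(loadFixture("table2"), "inconsistency")

  t3 <- loadFixture("table3")
  expect_equal(nrow(t3$parameters), 14L)  # 6+6 complexes + 2 apo
  expect_equal(t3$correlations$PTP1B["n_hbond", "g_bind"], -0.923)
  expect_true(isSymmetric(t3$correlations$DPP4))

  t4 <- suppressWarnings(loadFixture("table4"))
  expect_equal(nrow(t4$profiles), 12L)
  expect_true("g_bind" %in% names(t4$profiles))
  ## column-shifted sitagliptin row kept verbatim but flagged
  sita <- t4$profiles[t4$profiles$compound == "sitagliptin", ]
  expect_true(sita$flagInconsistent)
  expect_equal(sita$eta, sita$xi)  # the printed anomaly is preserved
  expect_equal(t4$correlations$PTP1B["xi", "g_bind"], -0.89)
  expect_equal(t4$correlations$DPP4["ea", "g_bind"], -0.93)

  t7 <- loadFixture("table7")
  expect_equal(t7$ptp1b[t7$parameter == "Q2" &
                          grepl("LOO", t7$section)], "0.873")

  t8 <- loadFixture("table8")
  expect_equal(nrow(t8), 12L)
  expect_equal(sum(t8$target == "PTP1B"), 6L)
  expect_equal(t8$mw[t8$name == "Diosmetin" & t8$target == "PTP1B"],
               300.26)
})
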