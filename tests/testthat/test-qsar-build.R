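test_that("preprocessing drops missing, constant and collinear columns", {
  gen <- makePlanted(n = 60, m = 10, k = 2, noiseSd = 0.1, seed = 21)
  X <- descriptorMatrix(gen$dataset)
  X[, "D0001"] <- 1                       # constant
  X[3, "D0002"] <- NA                     # missing value
  d <- qsarDataset(X, activity(gen$dataset))
  out <- preprocessDescriptors(d)
  expect_true(all(c("D0001", "D0002") %in% out$removed$descriptor))
  expect_equal(out$removed$reason[out$removed$descriptor == "D0001"],
               "variance")
  expect_equal(out$removed$reason[out$removed$descriptor == "D0002"],
               "missing")
  expect_false(any(c("D0001", "D0002") %in%
                     descriptorNames(out$dataset)))

  ## two identical columns: exactly one of the pair is removed
  X2 <- descriptorMatrix(gen$dataset)
  X2[, "D0003"] <- X2[, "D0004"]
  d2 <- qsarDataset(X2, activity(gen$dataset))
  out2 <- preprocessDescriptors(d2)
  expect_equal(sum(out2$removed$descriptor %in% c("D0003", "D0004")), 1L)

  expect_error(preprocessDescriptors(d[, "D0001"]), "every descriptor")
})

test_that("planted near-duplicates are removed at the documented cap", {
  gen <- genQsarDataset(nCompounds = 500, mDescriptors = 20,
                        kInformative = 3, collinearityRho = 0.99,
                        nRedundant = 3, noiseSd = 0.1, seed = 13)
  out <- preprocessDescriptors(gen$dataset, intercorrelationCap = 0.95)
  inter <- out$removed[out$removed$reason == "intercorrelation", ]
  expect_equal(nrow(inter), 3L)
  ## brute-force pair scan on the survivors confirms no pair above cap
  r <- abs(cor(descriptorMatrix(out$dataset)))
  diag(r) <- 0
  expect_lt(max(r), 0.95)
})

test_that("Kennard-Stone selects extremes first and is deterministic", {
  ## hand-executed example: points on a line at 0,1,2,3,10
  d <- qsarDataset(matrix(c(0, 1, 2, 3, 10), ncol = 1,
                          dimnames = list(NULL, "x")),
                   y = rep(0, 5), compounds = paste0("p", 1:5))
  sp <- kennardStoneSplit(d, nTrain = 3, autoscale = FALSE)
  expect_setequal(sp$train_ids, c("p1", "p5", "p4"))  # x = 0, 10, 3
  expect_setequal(sp$test_ids, c("p2", "p3"))

  expect_error(kennardStoneSplit(d, nTrain = 5), "nTrain")
  ## n - 1 training points leave a single interior point in the test set
  sp2 <- kennardStoneSplit(d, nTrain = 4, autoscale = FALSE)
  expect_length(sp2$test_ids, 1L)
})

test_that("Kennard-Stone is permutation-invariant and greedy max-min", {
  gen <- makePlanted(n = 60, m = 5, noiseSd = 0.1, seed = 31)
  d <- gen$dataset
  sp <- kennardStoneSplit(d, nTrain = 40)
  perm <- withr::with_seed(1, sample(60))
  sp2 <- kennardStoneSplit(d[perm, ], nTrain = 40)
  expect_setequal(sp$train_ids, sp2$train_ids)

  ## brute-force check of the greedy max-min property per iteration
  X <- scale(descriptorMatrix(d))
  D <- as.matrix(dist(X))
  sel <- match(sp$train_ids, compoundIds(d))
  expect_equal(D[sel[1], sel[2]], max(D))  # seed pair is the diameter
  for (step in 3:10) {
    prev <- sel[seq_len(step - 1)]
    minD <- apply(D[, prev, drop = FALSE], 1, min)
    minD[prev] <- -Inf
    expect_equal(unname(minD[sel[step]]), max(minD))
  }
})

test_that("fitMlr matches closed forms and the normal-equations oracle", {
  ## y = 2x + 1 exactly
  d <- qsarDataset(matrix(0:3, ncol = 1, dimnames = list(NULL, "x")),
                   y = c(1, 3, 5, 7))
  m <- fitMlr(d, "x")
  expect_equal(m@intercept, 1, tolerance = 1e-12)
  expect_equal(unname(coef(m)), 2, tolerance = 1e-12)

  ## independent linear-algebra oracle: explicit normal equations
  gen <- makePlanted(n = 50, m = 8, k = 8, noiseSd = 0.2, seed = 11)
  d2 <- gen$dataset
  m2 <- fitMlr(d2, descriptorNames(d2))
  X <- cbind(1, descriptorMatrix(d2))
  beta <- solve(t(X) %*% X, t(X) %*% activity(d2))
  expect_equal(unname(c(m2@intercept, coef(m2))), unname(drop(beta)),
               tolerance = 1e-10)
  sigma2 <- sum((activity(d2) - X %*% beta)^2) / (50 - 9)
  se <- sqrt(diag(sigma2 * solve(t(X) %*% X)))
  expect_equal(unname(c(m2@interceptSE, m2@coefSE)), unname(se),
               tolerance = 1e-10)

  ## residuals orthogonal to every design column
  res <- activity(d2) - applyModel(m2, d2, warnExtrapolation = FALSE)
  expect_lt(max(abs(t(X) %*% res)), 1e-8)

  ## rank deficiency is reported with the offending column
  X3 <- descriptorMatrix(d2)[, 1:3]
  X3[, 3] <- X3[, 1] + X3[, 2]
  d3 <- qsarDataset(X3, activity(d2))
  expect_error(fitMlr(d3, colnames(X3)), "collinear")
})

test_that("autoscaled fits predict identically on raw descriptors", {
  gen <- makePlanted(n = 40, m = 6, k = 3, noiseSd = 0.2, seed = 7)
  d <- gen$dataset
  sub <- descriptorNames(d)[1:4]
  m0 <- fitMlr(d, sub, autoscale = FALSE)
  m1 <- fitMlr(d, sub, autoscale = TRUE)
  expect_equal(applyModel(m1, d, warnExtrapolation = FALSE,
                          warnExtra = FALSE),
               applyModel(m0, d, warnExtrapolation = FALSE,
                          warnExtra = FALSE),
               tolerance = 1e-10)
})

test_that("GA selection respects its contracts", {
  gen <- makePlanted(n = 30, m = 5, k = 2, noiseSd = 0.3, seed = 17)
  ## m == equation length: the only subset, returned immediately
  res <- gaSelect(gen$dataset, gaConfig(equationLength = 5, seed = 1))
  expect_setequal(res$descriptors, descriptorNames(gen$dataset))
  expect_length(res$trace, 1L)

  expect_error(gaSelect(gen$dataset,
                        gaConfig(equationLength = 6, seed = 1)),
               "fewer distinct descriptors")
})

test_that("GA recovers a planted subset and its trace is monotone", {
  gen <- genQsarDataset(nCompounds = 100, mDescriptors = 30,
                        kInformative = 4, noiseSd = 0.1, seed = 23)
  cfg <- gaConfig(generations = 60, equationLength = 4, seed = 23)
  res <- gaSelect(gen$dataset, cfg)
  expect_true(all(diff(res$trace) >= 0))  # elitism
  expect_gte(sum(res$descriptors %in% gen$truth$informative), 3)
  ## reproducibility from the seed
  res2 <- gaSelect(gen$dataset, cfg)
  expect_identical(res$descriptors, res2$descriptors)

  ## noiseless with the true subset representable: Q2 reaches 1
  gen0 <- genQsarDataset(nCompounds = 80, mDescriptors = 15,
                         kInformative = 3, noiseSd = 0, seed = 29)
  res0 <- gaSelect(gen0$dataset,
                   gaConfig(generations = 200, equationLength = 3,
                            seed = 29))
  expect_equal(res0$fitness, 1, tolerance = 1e-9)
  expect_setequal(res0$descriptors, gen0$truth$informative)
})
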