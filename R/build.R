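## Model construction: descriptor preprocessing, Kennard-Stone
## partitioning, GA subset selection, OLS fitting.

## evaluate expr under a fixed seed without disturbing the caller's RNG
withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

#' Preprocess a descriptor matrix
#'
#' Removes, in order: columns containing any missing value; columns with
#' variance at or below `varianceFloor`; and, for every pair of remaining
#' columns with |Pearson r| above `intercorrelationCap`, the member with
#' the larger mean absolute correlation to all other remaining columns
#' (pairs are resolved most-correlated first; equal mean correlations drop
#' the later column). Column order is otherwise preserved.
#'
#' Thresholds follow conventional chemometrics practice; the removal log
#' makes every decision auditable.
#'
#' @param dataset a [QsarDataset-class].
#' @param varianceFloor columns with variance <= this are dropped
#'   (near-constant descriptors).
#' @param intercorrelationCap maximum tolerated |Pearson r| between two
#'   descriptors.
#' @return list with `dataset` (the reduced [QsarDataset-class]) and
#'   `removed` (data.frame: descriptor, reason, detail).
#' @examples
#' gen <- genQsarDataset(nCompounds = 30, mDescriptors = 10, seed = 1)
#' preprocessDescriptors(gen$dataset)$removed
#' @export
preprocessDescriptors <- function(dataset, varianceFloor = 1e-8,
                                  intercorrelationCap = 0.95) {
  X <- descriptorMatrix(dataset)
  log <- data.frame(descriptor = character(), reason = character(),
                    detail = character())
  addLog <- function(cols, reason, detail = "") {
    log <<- rbind(log, data.frame(descriptor = cols, reason = reason,
                                  detail = detail))
  }
  hasNA <- colnames(X)[colSums(is.na(X)) > 0]
  if (length(hasNA)) addLog(hasNA, "missing", "contains NA")
  keep <- setdiff(colnames(X), hasNA)
  v <- apply(X[, keep, drop = FALSE], 2, stats::var)
  lowVar <- keep[v <= varianceFloor]
  if (length(lowVar))
    addLog(lowVar, "variance",
           sprintf("variance %.3g <= %.3g", v[lowVar], varianceFloor))
  keep <- setdiff(keep, lowVar)
  if (length(keep) >= 2) {
    r <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(r) <- 0
    while (max(r) > intercorrelationCap) {
      idx <- which(r == max(r), arr.ind = TRUE)[1, ]
      i <- idx[1]; j <- idx[2]
      meanAbs <- rowMeans(r)
      drop <- if (meanAbs[i] > meanAbs[j]) i
              else if (meanAbs[j] > meanAbs[i]) j
              else max(i, j)
      other <- if (drop == i) j else i
      addLog(rownames(r)[drop], "intercorrelation",
             sprintf("|r| = %.4f with %s", r[i, j], rownames(r)[other]))
      r <- r[-drop, -drop, drop = FALSE]
      if (nrow(r) < 2) break
    }
    keep <- keep[keep %in% rownames(r)]
  }
  if (!length(keep))
    stop("preprocessing removed every descriptor column")
  list(dataset = dataset[, keep], removed = log)
}

#' Kennard-Stone training/test split
#'
#' The classic max-min-distance design: seed the training set with the two
#' most distant compounds in (optionally autoscaled) descriptor space,
#' then repeatedly add the compound whose minimum Euclidean distance to
#' the already-selected set is largest, until `nTrain` compounds are
#' selected. Deterministic; ties are broken by the lowest row index, so
#' the result is invariant to row shuffling up to that rule.
#'
#' @param dataset a [QsarDataset-class].
#' @param nTrain training-set size, `1 <= nTrain < n`.
#' @param autoscale center/scale descriptors before computing distances
#'   (default TRUE: descriptors have heterogeneous units).
#' @return list with `train_ids`, `test_ids` (disjoint, covering all
#'   compounds) and `method = "kennard_stone"`.
#' @examples
#' d <- qsarDataset(matrix(c(0, 1, 2, 3, 10), ncol = 1,
#'                         dimnames = list(NULL, "x")), y = rep(0, 5))
#' kennardStoneSplit(d, nTrain = 3, autoscale = FALSE)$train_ids
#' @export
kennardStoneSplit <- function(dataset, nTrain, autoscale = TRUE) {
  n <- nrow(descriptorMatrix(dataset))
  if (nTrain < 1 || nTrain >= n)
    stop("nTrain must satisfy 1 <= nTrain < n (= ", n, ")")
  X <- descriptorMatrix(dataset)
  if (autoscale) {
    s <- apply(X, 2, stats::sd)
    X <- scale(X, center = TRUE, scale = ifelse(s > 0, s, 1))
  }
  sq <- rowSums(X^2)
  distTo <- function(i)  # squared Euclidean distances of all rows to row i
    pmax(sq + sq[i] - 2 * drop(X %*% X[i, ]), 0)
  ## seed: the most distant pair (first such pair in scan order)
  best <- c(1L, 2L); bestD <- -Inf
  for (i in seq_len(n - 1)) {
    d <- distTo(i)
    d[seq_len(i)] <- -Inf
    j <- which.max(d)
    if (d[j] > bestD) { bestD <- d[j]; best <- c(i, j) }
  }
  sel <- best
  minDist <- pmin(distTo(best[1]), distTo(best[2]))
  minDist[best] <- -Inf
  while (length(sel) < nTrain) {
    nxt <- which.max(minDist)   # ties -> lowest index
    sel <- c(sel, nxt)
    minDist <- pmin(minDist, distTo(nxt))
    minDist[nxt] <- -Inf
  }
  ids <- compoundIds(dataset)
  ## train ids in selection order (seed pair first, then greedy adds)
  list(train_ids = ids[sel], test_ids = ids[-sel],
       method = "kennard_stone")
}

## ---- OLS core shared by fitMlr and the GA fitness functions ----

## returns fitted machinery for y ~ 1 + Xsub; design must be full rank
olsCore <- function(Xsub, y) {
  X <- cbind(`(Intercept)` = 1, Xsub)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qrX, y)
  res <- y - drop(X %*% coefs)
  h <- rowSums(qr.Q(qrX)^2)
  list(X = X, coef = coefs, residuals = res, hat = h, qr = qrX)
}

looStats <- function(core, y) {
  press <- sum((core$residuals / (1 - core$hat))^2)
  tss <- sum((y - mean(y))^2)
  list(press = press, q2 = 1 - press / tss,
       yLoo = y - core$residuals / (1 - core$hat))
}

#' Fit a multiple linear regression QSAR model
#'
#' Ordinary least squares with intercept on the given descriptor subset.
#' Coefficient standard errors come from the residual variance (n - p
#' denominator, p including the intercept) and the inverse normal-equations
#' matrix. With `autoscale = TRUE` descriptors are centered and scaled to
#' unit variance before fitting and the (center, scale) pairs are stored in
#' the model, so predictions on raw descriptor values are reproducible.
#'
#' @param dataset a [QsarDataset-class] (training set).
#' @param descriptors character vector of descriptor names to use.
#' @param autoscale store per-descriptor (center, scale) in the model and
#'   fit on the scaled design.
#' @return An [MlrModel-class].
#' @examples
#' d <- qsarDataset(matrix(0:3, ncol = 1, dimnames = list(NULL, "x")),
#'                  y = c(1, 3, 5, 7))
#' fitMlr(d, "x")
#' @export
fitMlr <- function(dataset, descriptors, autoscale = FALSE) {
  X <- descriptorMatrix(dataset)
  miss <- setdiff(descriptors, colnames(X))
  if (length(miss))
    stop("descriptor(s) not in dataset: ", paste(miss, collapse = ", "))
  y <- activity(dataset)
  n <- length(y)
  p <- length(descriptors) + 1L
  if (n <= p)
    stop("need more training compounds (", n, ") than model terms (", p,
         ")")
  Xsub <- X[, descriptors, drop = FALSE]
  scaling <- list()
  if (autoscale) {
    center <- colMeans(Xsub)
    scl <- apply(Xsub, 2, stats::sd)
    if (any(scl == 0))
      stop("cannot autoscale constant descriptor(s): ",
           paste(descriptors[scl == 0], collapse = ", "))
    Xsub <- scale(Xsub, center = center, scale = scl)
    scaling <- list(center = center, scale = scl)
  }
  core <- olsCore(Xsub, y)
  sigma2 <- sum(core$residuals^2) / (n - p)
  XtXinv <- chol2inv(qr.R(core$qr))
  se <- sqrt(sigma2 * diag(XtXinv))
  cf <- core$coef[-1]
  names(cf) <- descriptors
  seCf <- se[-1]
  names(seCf) <- descriptors
  new("MlrModel", intercept = unname(core$coef[1]),
      interceptSE = se[1], coefficients = cf, coefSE = seCf,
      scaling = scaling,
      training = list(n = n, yRange = range(y), yMean = mean(y)))
}

## GA fitness criteria (all maximized)
gaFitnessFun <- function(fitness, y) {
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  switch(fitness,
    q2_loo = function(core) {
      1 - sum((core$residuals / (1 - core$hat))^2) / tss
    },
    r2_adj = function(core) {
      p <- ncol(core$X)
      r2 <- 1 - sum(core$residuals^2) / tss
      1 - (1 - r2) * (n - 1) / (n - p)
    },
    mae = function(core) -mean(abs(core$residuals)))
}

#' Genetic-algorithm descriptor selection
#'
#' Searches fixed-size descriptor subsets for the one whose OLS model
#' maximizes the chosen fitness criterion. Chromosomes are descriptor
#' subsets of size `equationLength`; each generation the best `survivors`
#' chromosomes are carried over unchanged (elitist survival, so the
#' best-fitness trace is monotone non-decreasing) and parent the rest of
#' the population through single-point crossover over sorted gene lists
#' (duplicate genes repaired by resampling from unused descriptors) and
#' per-gene replacement mutation. Fitness values are cached per subset.
#' The run is fully reproducible from `config@seed` and stops early if the
#' criterion's theoretical maximum is reached (Q2 or r2 of 1, MAE of 0),
#' since no later generation can improve on it.
#'
#' @param dataset a [QsarDataset-class] (training set).
#' @param config a [GAConfig-class]; see [gaConfig()].
#' @param fitness `"q2_loo"` (leave-one-out Q2, the default), `"r2_adj"`
#'   or `"mae"` (negated mean absolute residual).
#' @return list with `descriptors` (the selected subset, in dataset
#'   column order), `fitness` (its score), `trace` (best fitness per
#'   generation) and `evaluations` (number of distinct subsets scored).
#' @examples
#' gen <- genQsarDataset(nCompounds = 60, mDescriptors = 12,
#'                       kInformative = 3, noiseSd = 0, seed = 2)
#' cfg <- gaConfig(generations = 30, equationLength = 3, seed = 2)
#' gaSelect(gen$dataset, cfg)$descriptors
#' @export
gaSelect <- function(dataset, config = gaConfig(),
                     fitness = c("q2_loo", "r2_adj", "mae")) {
  fitness <- match.arg(fitness)
  validObject(config)
  X <- descriptorMatrix(dataset)
  y <- activity(dataset)
  m <- ncol(X)
  L <- config@equationLength
  if (m < L)
    stop("fewer distinct descriptors (", m, ") than equation length (",
         L, ")")
  if (length(y) <= L + 1L)
    stop("training set too small for equation length ", L)
  fitFun <- gaFitnessFun(fitness, y)
  fitMax <- if (fitness == "mae") 0 else 1
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  score <- function(genes) {
    key <- paste(genes, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- fitFun(olsCore(X[, genes, drop = FALSE], y))
    evals <<- evals + 1L
    cache[[key]] <- f
    f
  }
  if (m == L) {   # only one subset exists: generation 0 answer
    genes <- sort(seq_len(m))
    return(list(descriptors = colnames(X)[genes], fitness = score(genes),
                trace = score(genes), evaluations = evals))
  }
  sampleFrom <- function(pool, k) pool[sample.int(length(pool), k)]
  withSeed(config@seed, {
    pop <- replicate(config@populationInit,
                     sort(sample.int(m, L)), simplify = FALSE)
    trace <- numeric(0)
    repair <- function(genes) {
      genes <- unique(genes)
      if (length(genes) < L)
        genes <- c(genes, sampleFrom(setdiff(seq_len(m), genes),
                                     L - length(genes)))
      sort(genes)
    }
    mutate <- function(genes) {
      hit <- which(stats::runif(L) < config@mutationProb)
      if (length(hit)) {
        pool <- setdiff(seq_len(m), genes)
        hit <- hit[seq_len(min(length(hit), length(pool)))]
        genes[hit] <- sampleFrom(pool, length(hit))
      }
      sort(genes)
    }
    crossover <- function(p1, p2) {
      cut <- sample.int(L - 1L, 1L)
      repair(c(p1[seq_len(cut)], p2[seq(cut + 1L, L)]))
    }
    for (gen in seq_len(config@generations)) {
      fit <- vapply(pop, score, numeric(1))
      ord <- order(fit, decreasing = TRUE)
      trace <- c(trace, fit[ord[1]])
      if (fit[ord[1]] >= fitMax - 1e-12) break
      elites <- pop[ord[seq_len(config@survivors)]]
      children <- lapply(seq_len(config@populationInit - config@survivors),
        function(i) {
          par <- sample(config@survivors, 2, replace = TRUE)
          child <- if (stats::runif(1) < config@crossoverProb)
            crossover(elites[[par[1]]], elites[[par[2]]])
          else elites[[par[1]]]
          mutate(child)
        })
      pop <- c(elites, children)
    }
    fit <- vapply(pop, score, numeric(1))
    best <- pop[[which.max(fit)]]
    list(descriptors = colnames(X)[best], fitness = max(fit),
         trace = trace, evaluations = evals)
  })
}
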