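## Internal/external validation battery, regression-through-origin
## metrics, rm2 metrics, Golbraikh-Tropsha criteria, applicability domain.

## rebuild the (scaled) training design for a model on a dataset
modelDesign <- function(model, dataset) {
  X <- descriptorMatrix(dataset)
  miss <- setdiff(names(model@coefficients), colnames(X))
  if (length(miss))
    stop("model descriptor(s) absent from dataset: ",
         paste(miss, collapse = ", "))
  Xsub <- X[, names(model@coefficients), drop = FALSE]
  if (length(model@scaling))
    Xsub <- scale(Xsub,
                  center = model@scaling$center[colnames(Xsub)],
                  scale = model@scaling$scale[colnames(Xsub)])
  Xsub
}

#' Internal (training-set) validation metrics
#'
#' Computes r2, adjusted r2, SEE (residual standard error, n - p
#' denominator with p counting the intercept), PRESS (sum of squared
#' leave-one-out prediction errors via the leverage shortcut
#' e_i / (1 - h_i)), Q2_LOO = 1 - PRESS / TSS, and the rm2 metrics of the
#' LOO predictions against the observed activities.
#'
#' @param model an [MlrModel-class] fitted on `dataset` (by OLS; the
#'   leverage shortcut assumes least-squares residuals).
#' @param dataset the training [QsarDataset-class].
#' @return A [ValidationReport-class] with the `internal` block filled.
#' @export
internalMetrics <- function(model, dataset) {
  y <- activity(dataset)
  n <- length(y)
  p <- length(model@coefficients) + 1L
  if (n <= p) stop("n (", n, ") must exceed model terms p (", p, ")")
  core <- olsCore(modelDesign(model, dataset), y)
  tss <- sum((y - mean(y))^2)
  rss <- sum(core$residuals^2)
  loo <- looStats(core, y)
  rm2 <- rm2Metrics(y, loo$yLoo)
  r2 <- 1 - rss / tss
  internal <- c(
    r2 = r2,
    r2_adj = 1 - (1 - r2) * (n - 1) / (n - p),
    see = sqrt(rss / (n - p)),
    press = loo$press,
    q2_loo = loo$q2,
    avg_rm2_loo = rm2[["avg_rm2"]],
    delta_rm2_loo = rm2[["delta_rm2"]])
  new("ValidationReport", internal = internal, external = numeric(),
      maeVerdict = NA_character_, gtChecks = data.frame())
}

#' Regression-through-origin slopes and coefficients
#'
#' For observed and predicted activity vectors, computes the
#' through-origin slopes `k = sum(yObs*yPred)/sum(yPred^2)` and
#' `kPrime = sum(yObs*yPred)/sum(yObs^2)`, and the through-origin
#' determination coefficients
#' `r0_2 = 1 - sum((yPred - k*yPred)^2) / sum((yPred - mean(yPred))^2)`
#' and its axis-inverted counterpart
#' `r0_prime_2 = 1 - sum((yObs - kPrime*yObs)^2) / sum((yObs - mean(yObs))^2)`.
#' These can be negative for poor fits; no clamping is applied here.
#'
#' @param yObs,yPred numeric vectors of equal length >= 3 with nonzero
#'   variance.
#' @return named numeric vector `(r0_2, r0_prime_2, k, k_prime)`.
#' @examples
#' regressionThroughOrigin(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' @export
regressionThroughOrigin <- function(yObs, yPred) {
  if (length(yObs) != length(yPred) || length(yObs) < 3)
    stop("yObs and yPred must have equal length >= 3")
  if (stats::var(yObs) == 0 || stats::var(yPred) == 0)
    stop("zero variance in yObs or yPred")
  sOP <- sum(yObs * yPred)
  if (sum(yPred^2) == 0 || sum(yObs^2) == 0)
    stop("zero denominator in through-origin slope")
  k <- sOP / sum(yPred^2)
  kPrime <- sOP / sum(yObs^2)
  r0 <- 1 - sum((yPred - k * yPred)^2) / sum((yPred - mean(yPred))^2)
  r0p <- 1 - sum((yObs - kPrime * yObs)^2) / sum((yObs - mean(yObs))^2)
  c(r0_2 = r0, r0_prime_2 = r0p, k = k, k_prime = kPrime)
}

#' rm2 metrics
#'
#' Modified r2 measures penalizing divergence between the ordinary
#' squared correlation r2 and its through-origin counterparts:
#' `rm2 = r2 * (1 - sqrt(r2 - r0_2))` and
#' `rm2' = r2 * (1 - sqrt(r2 - r0_prime_2))`, with their average and
#' absolute difference. With `scale = TRUE` both vectors are first
#' min-max scaled to the unit interval using their combined range (the convention
#' used for "after scaling" external rm2 blocks). The through-origin
#' coefficients are not bounded by r2, so the radicand can be negative;
#' it is then clamped at 0 (making rm2 = r2) and flagged via the
#' `"clamped"` attribute.
#'
#' @param yObs,yPred numeric vectors of equal length >= 3.
#' @param scale min-max scale to the unit interval on the combined range first.
#' @return named numeric vector `(rm2, rm2_prime, avg_rm2, delta_rm2)`.
#' @export
rm2Metrics <- function(yObs, yPred, scale = FALSE) {
  if (length(yObs) != length(yPred) || length(yObs) < 3)
    stop("yObs and yPred must have equal length >= 3")
  if (scale) {
    rng <- range(c(yObs, yPred))
    if (diff(rng) == 0) stop("cannot min-max scale constant data")
    yObs <- (yObs - rng[1]) / diff(rng)
    yPred <- (yPred - rng[1]) / diff(rng)
  }
  r2 <- stats::cor(yObs, yPred)^2
  ro <- regressionThroughOrigin(yObs, yPred)
  rad <- c(r2 - ro[["r0_2"]], r2 - ro[["r0_prime_2"]])
  clamped <- rad < 0
  rad[clamped] <- 0
  rm2 <- r2 * (1 - sqrt(rad[1]))
  rm2p <- r2 * (1 - sqrt(rad[2]))
  out <- c(rm2 = rm2, rm2_prime = rm2p,
           avg_rm2 = (rm2 + rm2p) / 2, delta_rm2 = abs(rm2 - rm2p))
  attr(out, "clamped") <- any(clamped)
  out
}

#' External (test-set) validation metrics
#'
#' Computes, on the test set: squared Pearson r2 of observed vs predicted,
#' the through-origin metrics of [regressionThroughOrigin()], RMSEP,
#' `Q2_f1 = 1 - sum((yPred - yObs)^2) / sum((yObs - yBarTrain)^2)` and
#' `Q2_f2` (same with the test-set mean), unscaled and min-max-scaled rm2
#' metrics, and the MAE-based quality judgement on the best 95% of test
#' compounds: the `ceiling(0.05 n)` largest absolute errors are dropped,
#' and the verdict (relative to the training activity range) is GOOD when
#' `MAE95 <= 0.1*range` and `MAE95 + 3*SD95 <= 0.2*range`, BAD when
#' `MAE95 > 0.15*range` or `MAE95 + 3*SD95 > 0.25*range`, else MODERATE.
#'
#' @param model an [MlrModel-class].
#' @param dataset the test [QsarDataset-class].
#' @param trainMean training-set activity mean for Q2_f1; defaults to
#'   the mean stored in the model by [fitMlr()]. Models restored with
#'   [readModelJson()] do not carry it (the JSON schema stores only n
#'   and the activity range), so pass it explicitly for those.
#' @return A [ValidationReport-class] with the `external` block and
#'   `maeVerdict` filled. With fewer than 3 test compounds the metrics
#'   carry attribute `unreliable = TRUE` and a warning is raised.
#' @export
externalMetrics <- function(model, dataset, trainMean = NULL) {
  y <- activity(dataset)
  if (!length(y)) stop("empty test set")
  yPred <- applyModel(model, dataset, warnExtrapolation = FALSE,
                      warnExtra = FALSE)
  if (is.null(trainMean)) trainMean <- model@training$yMean
  if (is.null(trainMean))
    stop("trainMean not supplied and not stored in the model")
  unreliable <- length(y) < 3
  if (unreliable)
    warning("fewer than 3 test compounds; external metrics unreliable")
  err <- yPred - y
  rmsep <- sqrt(mean(err^2))
  q2f1 <- 1 - sum(err^2) / sum((y - trainMean)^2)
  q2f2 <- 1 - sum(err^2) / sum((y - mean(y))^2)
  if (unreliable) {
    ext <- c(r2 = NA_real_, r0_2 = NA_real_, r0_prime_2 = NA_real_,
             k = NA_real_, k_prime = NA_real_, rmsep = rmsep,
             q2_f1 = q2f1, q2_f2 = q2f2, avg_rm2 = NA_real_,
             delta_rm2 = NA_real_, mae_95 = mean(abs(err)),
             sd_95 = stats::sd(abs(err)))
    attr(ext, "unreliable") <- TRUE
    return(new("ValidationReport", internal = numeric(), external = ext,
               maeVerdict = NA_character_, gtChecks = data.frame()))
  }
  ro <- regressionThroughOrigin(y, yPred)
  rm2s <- rm2Metrics(y, yPred, scale = TRUE)
  ## MAE on the best 95%: drop the ceiling(5%) largest absolute errors
  nDrop <- ceiling(0.05 * length(y))
  kept <- sort(abs(err))[seq_len(length(y) - nDrop)]
  mae95 <- mean(kept)
  sd95 <- stats::sd(kept)
  yRange <- diff(model@training$yRange)
  verdict <- if (!is.finite(yRange)) NA_character_
  else if (mae95 <= 0.1 * yRange && mae95 + 3 * sd95 <= 0.2 * yRange)
    "GOOD"
  else if (mae95 > 0.15 * yRange || mae95 + 3 * sd95 > 0.25 * yRange)
    "BAD"
  else "MODERATE"
  ext <- c(r2 = stats::cor(y, yPred)^2, ro[c("r0_2", "r0_prime_2")],
           k = ro[["k"]], k_prime = ro[["k_prime"]], rmsep = rmsep,
           q2_f1 = q2f1, q2_f2 = q2f2,
           avg_rm2 = rm2s[["avg_rm2"]], delta_rm2 = rm2s[["delta_rm2"]],
           mae_95 = mae95, sd_95 = sd95)
  names(ext)[2:3] <- c("r0_2", "r0_prime_2")
  new("ValidationReport", internal = numeric(), external = ext,
      maeVerdict = verdict, gtChecks = data.frame())
}

#' Golbraikh-Tropsha predictivity criteria
#'
#' Evaluates the five acceptability conditions for an externally validated
#' QSAR model:
#' \enumerate{
#'   \item `Q2 > 0.5` (leave-one-out, training set)
#'   \item `r2 > 0.6` (test set)
#'   \item `(r2 - r0_2)/r2 < 0.1` with `0.85 <= k <= 1.15`, or the
#'     axis-inverted branch `(r2 - r0_prime_2)/r2 < 0.1` with
#'     `0.85 <= k_prime <= 1.15`
#'   \item `|r0_2 - r0_prime_2| < 0.3`
#'   \item `r0_2` or `r0_prime_2` close to `r2` (the smaller of the two
#'     relative gaps below 0.1)
#' }
#'
#' @param report a [ValidationReport-class] with both blocks filled, or a
#'   named list/vector providing `q2`, `r2`, `r0_2`, `r0_prime_2`, `k`,
#'   `k_prime`.
#' @return data.frame (criterion, value, threshold, passed); attribute
#'   `"details"` carries the derived ratios and slopes.
#' @examples
#' golbraikhTropshaCheck(list(q2 = 0.873, r2 = 0.867, r0_2 = 0.862,
#'                            r0_prime_2 = 0.814, k = 1.001,
#'                            k_prime = 0.998))
#' @export
golbraikhTropshaCheck <- function(report) {
  if (is(report, "ValidationReport")) {
    vals <- list(q2 = report@internal[["q2_loo"]],
                 r2 = report@external[["r2"]],
                 r0_2 = report@external[["r0_2"]],
                 r0_prime_2 = report@external[["r0_prime_2"]],
                 k = report@external[["k"]],
                 k_prime = report@external[["k_prime"]])
  } else vals <- as.list(report)
  need <- c("q2", "r2", "r0_2", "r0_prime_2", "k", "k_prime")
  miss <- need[!vapply(need, function(f)
    !is.null(vals[[f]]) && is.finite(vals[[f]]), logical(1))]
  if (length(miss))
    stop("missing field(s) for Golbraikh-Tropsha check: ",
         paste(miss, collapse = ", "))
  ratio <- (vals$r2 - vals$r0_2) / vals$r2
  ratioP <- (vals$r2 - vals$r0_prime_2) / vals$r2
  branch1 <- ratio < 0.1 && vals$k >= 0.85 && vals$k <= 1.15
  branch2 <- ratioP < 0.1 && vals$k_prime >= 0.85 && vals$k_prime <= 1.15
  checks <- data.frame(
    criterion = c("I", "II", "III", "IV", "V"),
    description = c(
      "Q2 > 0.5", "r2 > 0.6",
      "(r2-r0_2)/r2 < 0.1 & 0.85<=k<=1.15 (or primed branch)",
      "|r0_2 - r0_prime_2| < 0.3",
      "r0_2 or r0_prime_2 close to r2"),
    value = c(vals$q2, vals$r2, min(ratio, ratioP),
              abs(vals$r0_2 - vals$r0_prime_2), min(ratio, ratioP)),
    threshold = c("> 0.5", "> 0.6", "< 0.1 (with slope in [0.85,1.15])",
                  "< 0.3", "< 0.1"),
    passed = c(vals$q2 > 0.5, vals$r2 > 0.6, branch1 || branch2,
               abs(vals$r0_2 - vals$r0_prime_2) < 0.3,
               min(ratio, ratioP) < 0.1))
  attr(checks, "details") <- c(
    ratio_r2_r02 = ratio, ratio_r2_r0prime2 = ratioP,
    k = vals$k, k_prime = vals$k_prime,
    abs_r02_minus_r0prime2 = abs(vals$r0_2 - vals$r0_prime_2))
  checks
}

#' Run the full validation battery
#'
#' Convenience wrapper: internal metrics on the training set, external
#' metrics on the test set, and the Golbraikh-Tropsha criterion table,
#' merged into one report.
#'
#' @param model an [MlrModel-class].
#' @param train,test training and test [QsarDataset-class] objects.
#' @return A [ValidationReport-class] with every slot filled.
#' @export
validateModel <- function(model, train, test) {
  int <- internalMetrics(model, train)
  ext <- externalMetrics(model, test)
  rep <- new("ValidationReport", internal = int@internal,
             external = ext@external, maeVerdict = ext@maeVerdict,
             gtChecks = data.frame())
  rep@gtChecks <- golbraikhTropshaCheck(rep)
  rep
}

#' Leverage-based applicability domain (Williams plot table)
#'
#' Leverages are `h_i = x_i' (X'X)^-1 x_i` with X the training design on
#' the model descriptors (plus intercept, on the model's scaling). The
#' structural domain is bounded by the warning leverage `h* = 3p/n`
#' (p = descriptors + 1); the response domain by standardized residuals
#' within +/- `residualLimit`. Training residuals are standardized by the
#' training SEE; query residuals by the query-set RMSEP (each set's own
#' error scale).
#'
#' @param model an [MlrModel-class].
#' @param train the training [QsarDataset-class].
#' @param query optional [QsarDataset-class] of further compounds
#'   (e.g. the test set) to place in the domain.
#' @param residualLimit standardized-residual band half-width.
#' @return An [AdReport-class].
#' @export
applicabilityDomain <- function(model, train, query = NULL,
                                residualLimit = 3) {
  y <- activity(train)
  Xs <- modelDesign(model, train)
  core <- olsCore(Xs, y)
  p <- ncol(core$X)
  n <- nrow(core$X)
  XtXinv <- chol2inv(qr.R(core$qr))
  see <- sqrt(sum(core$residuals^2) / (n - p))
  hStar <- 3 * p / n
  tab <- data.frame(id = compoundIds(train), leverage = core$hat,
                    stdResidual = core$residuals / see, set = "train")
  if (!is.null(query)) {
    Xq <- cbind(1, modelDesign(model, query))
    hq <- rowSums((Xq %*% XtXinv) * Xq)
    resq <- activity(query) - applyModel(model, query,
                                         warnExtrapolation = FALSE,
                                         warnExtra = FALSE)
    rmsep <- sqrt(mean(resq^2))
    tab <- rbind(tab, data.frame(id = compoundIds(query), leverage = hq,
                                 stdResidual = resq / rmsep,
                                 set = "query"))
  }
  tab$inDomain <- tab$leverage <= hStar &
    abs(tab$stdResidual) <= residualLimit
  new("AdReport", table = tab, hStar = hStar,
      residualLimit = residualLimit, p = as.integer(p),
      nTrain = as.integer(n))
}

#' Export a Williams-plot table as TSV
#'
#' Columns: id, leverage, std_residual, set, in_domain.
#'
#' @param adReport an [AdReport-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeWilliamsTsv <- function(adReport, path) {
  tab <- adReport@table
  names(tab) <- c("id", "leverage", "std_residual", "set", "in_domain")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Williams plot
#'
#' Standardized residuals against leverages with the warning-leverage and
#' residual-band boundaries.
#'
#' @param adReport an [AdReport-class].
#' @param ... passed to [graphics::plot()].
#' @return `adReport`, invisibly.
#' @export
plotWilliams <- function(adReport, ...) {
  tab <- adReport@table
  sets <- factor(tab$set, levels = unique(tab$set))
  graphics::plot(tab$leverage, tab$stdResidual,
                 col = as.integer(sets), pch = as.integer(sets),
                 xlab = "leverage h", ylab = "standardized residual",
                 ylim = range(c(tab$stdResidual,
                                adReport@residualLimit * c(-1.2, 1.2))),
                 ...)
  graphics::abline(v = adReport@hStar, lty = 2)
  graphics::abline(h = c(-1, 1) * adReport@residualLimit, lty = 3)
  graphics::legend("topright", legend = levels(sets),
                   col = seq_along(levels(sets)),
                   pch = seq_along(levels(sets)), bty = "n")
  invisible(adReport)
}
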