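## Seeded generators emulating the statistical structure of each input
## class: descriptor matrices with a planted sparse linear signal,
## log-logistic inhibition curves, and energy tables obeying the
## thermodynamic cycle. All are pure functions of their arguments and the
## seed (the caller's RNG state is left untouched).

#' Generate a synthetic QSAR dataset with a planted linear signal
#'
#' Descriptor columns are standard normal. `kInformative` randomly placed
#' columns carry the signal: `y = intercept + X_inf %*% trueCoefficients
#' + N(0, noiseSd)`. `nRedundant` further columns are rho-correlated noisy
#' copies of informative columns (`rho*x + sqrt(1-rho^2)*noise`),
#' emulating the strong intercorrelation of real descriptor families;
#' remaining columns are pure noise. With `noiseSd = 0` and no
#' redundancy, OLS on the informative columns reproduces
#' `trueCoefficients` to machine precision.
#'
#' Defaults mirror a realistic inhibitor-modeling campaign: a few hundred
#' compounds, several hundred descriptors, a sparse signal of 8
#' descriptors (the usual published equation length), residual noise of
#' 0.2 pIC50 units and an intercept of 6, centering activities at a
#' realistic pIC50 magnitude.
#'
#' @param nCompounds,mDescriptors dataset dimensions.
#' @param kInformative number of signal-carrying descriptors
#'   (`<= mDescriptors`).
#' @param trueCoefficients length-`kInformative` coefficient vector;
#'   default alternating signs with magnitudes 1.5 down to 0.5.
#' @param intercept activity intercept.
#' @param noiseSd residual standard deviation on pIC50 (>= 0).
#' @param collinearityRho correlation used for redundant copies
#'   (|rho| < 1).
#' @param nRedundant number of redundant copies to plant (0 disables).
#' @param seed integer seed; same (spec, seed) gives bit-identical
#'   output.
#' @return list with `dataset` (a [QsarDataset-class]) and `truth`
#'   (informative names, coefficients, intercept, noiseSd, redundant-copy
#'   map).
#' @examples
#' gen <- genQsarDataset(nCompounds = 50, mDescriptors = 10,
#'                       kInformative = 2, seed = 1)
#' gen$truth$informative
#' @export
genQsarDataset <- function(nCompounds = 398, mDescriptors = 564,
                           kInformative = 8, trueCoefficients = NULL,
                           intercept = 6, noiseSd = 0.2,
                           collinearityRho = 0.9, nRedundant = 0,
                           seed = 1) {
  if (kInformative > mDescriptors)
    stop("kInformative must not exceed mDescriptors")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (abs(collinearityRho) >= 1) stop("|collinearityRho| must be < 1")
  if (nRedundant > mDescriptors - kInformative)
    stop("not enough columns for ", nRedundant, " redundant copies")
  if (is.null(trueCoefficients))
    trueCoefficients <- (-1)^(seq_len(kInformative) - 1) *
      seq(1.5, 0.5, length.out = kInformative)
  if (length(trueCoefficients) != kInformative)
    stop("trueCoefficients must have length kInformative")
  withSeed(seed, {
    dn <- sprintf("D%04d", seq_len(mDescriptors))
    X <- matrix(stats::rnorm(nCompounds * mDescriptors), nCompounds,
                mDescriptors, dimnames = list(NULL, dn))
    inf <- sort(sample.int(mDescriptors, kInformative))
    red <- integer(0)
    redSrc <- integer(0)
    if (nRedundant > 0) {
      red <- sort(sample(setdiff(seq_len(mDescriptors), inf), nRedundant))
      redSrc <- inf[1 + (seq_len(nRedundant) - 1) %% kInformative]
      for (i in seq_len(nRedundant))
        X[, red[i]] <- collinearityRho * X[, redSrc[i]] +
          sqrt(1 - collinearityRho^2) * stats::rnorm(nCompounds)
    }
    y <- intercept + drop(X[, inf, drop = FALSE] %*% trueCoefficients) +
      stats::rnorm(nCompounds, sd = noiseSd)
    truth <- list(informative = dn[inf],
                  coefficients = stats::setNames(trueCoefficients, dn[inf]),
                  intercept = intercept, noiseSd = noiseSd,
                  redundant = stats::setNames(dn[redSrc], dn[red]))
    list(dataset = qsarDataset(X, y), truth = truth)
  })
}

#' Generate synthetic dose-response records
#'
#' Percentage inhibition follows the log-logistic curve
#' `bottom + (top - bottom) / (1 + (ic50/c)^hill)` with independent
#' Gaussian replicate noise. At `c = ic50` the noiseless response is the
#' midpoint of `bottom` and `top` (the definition of IC50); as
#' `c -> Inf` it approaches `top`.
#'
#' @param ic50 true IC50 (same unit as `concentrations`, > 0).
#' @param hill Hill slope.
#' @param top,bottom response asymptotes (% inhibition).
#' @param concentrations strictly positive concentration vector.
#' @param noiseSd replicate noise SD (% inhibition).
#' @param nReplicates replicates per concentration.
#' @param seed integer seed.
#' @return data.frame (concentration, replicate, inhibition) with the
#'   generating parameters in `attr(, "truth")`.
#' @examples
#' genDoseResponse(ic50 = 27.26, concentrations = c(10, 30, 90), seed = 1)
#' @export
genDoseResponse <- function(ic50, hill = 1, top = 100, bottom = 0,
                            concentrations, noiseSd = 0,
                            nReplicates = 1, seed = 1) {
  if (ic50 <= 0) stop("ic50 must be positive")
  if (any(concentrations <= 0))
    stop("concentrations must be strictly positive")
  withSeed(seed, {
    mean <- bottom + (top - bottom) / (1 + (ic50 / concentrations)^hill)
    out <- data.frame(
      concentration = rep(concentrations, each = nReplicates),
      replicate = rep(seq_len(nReplicates), length(concentrations)),
      inhibition = rep(mean, each = nReplicates) +
        stats::rnorm(length(concentrations) * nReplicates, sd = noiseSd))
    attr(out, "truth") <- list(ic50 = ic50, hill = hill, top = top,
                               bottom = bottom, noiseSd = noiseSd)
    out
  })
}

#' Generate a synthetic MM-GBSA energy table
#'
#' Component terms are drawn around realistic centers (vdW -30, elec
#' -50, GB 60, surf -4 kcal/mol) with spread `componentSd`; the sums
#' `g_gas`, `g_solv`, `g_bind` are computed exactly, so every row passes
#' [validateThermoCycle()] with tolerance 0 by construction.
#'
#' @param nComplexes number of rows (>= 1).
#' @param componentSd spread of each drawn component (kcal/mol).
#' @param seed integer seed.
#' @return data.frame in the layout of `loadFixture("table2")` (values
#'   only, no spreads).
#' @export
genEnergyTable <- function(nComplexes, componentSd = 10, seed = 1) {
  if (nComplexes < 1) stop("nComplexes must be >= 1")
  withSeed(seed, {
    comp <- data.frame(
      complex = sprintf("complex%02d", seq_len(nComplexes)),
      e_vdw = stats::rnorm(nComplexes, -30, componentSd),
      e_elec = stats::rnorm(nComplexes, -50, componentSd),
      e_gb = stats::rnorm(nComplexes, 60, componentSd),
      e_surf = stats::rnorm(nComplexes, -4, componentSd / 10))
    cbind(comp, aggregateComponents(comp$e_vdw, comp$e_elec, comp$e_gb,
                                    comp$e_surf))
  })
}
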