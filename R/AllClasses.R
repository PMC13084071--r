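#' @import methods
NULL

#' QsarDataset: a descriptor matrix with activities
#'
#' The substrate of the whole modeling chain: a numeric matrix of molecular
#' descriptors (compounds in rows, named descriptors in columns) together
#' with a pIC50 activity vector (-log10 of the molar IC50) and unique
#' compound identifiers.
#'
#' Missing descriptor values are tolerated at construction (they are what
#' [preprocessDescriptors()] removes); activities must be finite.
#'
#' @slot compounds character vector of unique compound identifiers, one per
#'   row of `X`.
#' @slot X numeric matrix of descriptor values with unique column names.
#' @slot y numeric vector of pIC50 activities, parallel to `compounds`.
#'
#' @aliases compoundIds,QsarDataset-method descriptorNames,QsarDataset-method
#'   descriptorMatrix,QsarDataset-method activity,QsarDataset-method
#' @seealso [qsarDataset()], [readQsarCsv()], [genQsarDataset()]
#' @export
setClass("QsarDataset",
  slots = c(compounds = "character", X = "matrix", y = "numeric"))

setValidity("QsarDataset", function(object) {
  msg <- character()
  n <- length(object@compounds)
  if (nrow(object@X) != n)
    msg <- c(msg, "nrow(X) must equal length(compounds)")
  if (length(object@y) != n)
    msg <- c(msg, "length(y) must equal length(compounds)")
  if (anyDuplicated(object@compounds))
    msg <- c(msg, sprintf("duplicate compound ids: %s",
      paste(unique(object@compounds[duplicated(object@compounds)]),
            collapse = ", ")))
  if (is.null(colnames(object@X)) && ncol(object@X) > 0)
    msg <- c(msg, "X must have column (descriptor) names")
  if (!is.null(colnames(object@X)) && anyDuplicated(colnames(object@X)))
    msg <- c(msg, "descriptor names must be unique")
  if (!is.numeric(object@X))
    msg <- c(msg, "X must be numeric")
  if (length(object@y) && !all(is.finite(object@y)))
    msg <- c(msg, "activities (y) must all be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a QsarDataset
#'
#' @param X numeric matrix (compounds x descriptors) with column names.
#' @param y numeric pIC50 vector.
#' @param compounds compound identifiers; defaults to rownames of `X`
#'   or `cmpd1..cmpdn`.
#' @return A [QsarDataset-class] object.
#' @examples
#' X <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("D", 1:4)))
#' qsarDataset(X, y = rnorm(5))
#' @export
qsarDataset <- function(X, y, compounds = NULL) {
  X <- as.matrix(X)
  if (is.null(compounds))
    compounds <- if (!is.null(rownames(X))) rownames(X)
                 else paste0("cmpd", seq_len(nrow(X)))
  new("QsarDataset", compounds = as.character(compounds), X = X,
      y = as.numeric(y))
}

#' MlrModel: a fitted multiple linear regression QSAR model
#'
#' Holds the intercept and per-descriptor coefficients with their standard
#' errors, optional per-descriptor centering/scaling applied before the
#' linear form, and a summary of the training data (n and activity range)
#' used for extrapolation flagging.
#'
#' @slot intercept,interceptSE numeric(1): intercept and its standard error.
#' @slot coefficients named numeric vector of descriptor coefficients.
#' @slot coefSE standard errors, parallel to `coefficients`.
#' @slot scaling empty list, or `list(center=, scale=)` of named numeric
#'   vectors covering every model descriptor; predictions first apply
#'   `(x - center)/scale`.
#' @slot training `list(n=, yRange=c(min,max))` for the training set.
#' @seealso [fitMlr()], [applyModel()], [writeModelJson()]
#' @export
setClass("MlrModel",
  slots = c(intercept = "numeric", interceptSE = "numeric",
            coefficients = "numeric", coefSE = "numeric",
            scaling = "list", training = "list"))

setValidity("MlrModel", function(object) {
  msg <- character()
  cf <- object@coefficients
  if (length(cf) == 0L)
    msg <- c(msg, "model must have at least one descriptor coefficient")
  if (is.null(names(cf)) || anyDuplicated(names(cf)) || any(names(cf) == ""))
    msg <- c(msg, "coefficients must have unique non-empty names")
  if (length(object@coefSE) != length(cf) ||
      !identical(names(object@coefSE), names(cf)))
    msg <- c(msg, "coefSE must parallel coefficients (same names, same order)")
  if (length(object@scaling)) {
    need <- c("center", "scale")
    if (!all(need %in% names(object@scaling))) {
      msg <- c(msg, "scaling must contain 'center' and 'scale'")
    } else if (!all(names(cf) %in% names(object@scaling$center)) ||
               !all(names(cf) %in% names(object@scaling$scale))) {
      msg <- c(msg, "scaling must cover every model descriptor")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ValidationReport: the internal/external validation battery
#'
#' Container for every metric of the validation battery: training-set
#' statistics (r2, adjusted r2, SEE, PRESS, leave-one-out Q2 and LOO rm2
#' metrics), external test-set statistics (r2, regression-through-origin
#' r0^2 / r0'^2 / k / k', RMSEP, Q2_f1, Q2_f2, rm2 metrics, MAE/SD on the
#' best 95% of predictions), the MAE-based quality verdict, and the
#' Golbraikh-Tropsha criterion table.
#'
#' Either block may be empty when only one half of the battery has been
#' computed (see [internalMetrics()] / [externalMetrics()]).
#'
#' @slot internal named numeric vector of training-set metrics.
#' @slot external named numeric vector of test-set metrics.
#' @slot maeVerdict character(1): "GOOD", "MODERATE", "BAD" or NA.
#' @slot gtChecks data.frame of Golbraikh-Tropsha criteria
#'   (criterion, value, threshold, passed), possibly empty.
#' @seealso [validateModel()], [golbraikhTropshaCheck()]
#' @export
setClass("ValidationReport",
  slots = c(internal = "numeric", external = "numeric",
            maeVerdict = "character", gtChecks = "data.frame"))

#' AdReport: leverage-based applicability domain
#'
#' Per-compound leverages and standardized residuals against the warning
#' leverage h* = 3p/n and the +/-3 residual band: the table behind a
#' Williams plot.
#'
#' @slot table data.frame with columns id, leverage, stdResidual, set
#'   ("train"/"query"), inDomain.
#' @slot hStar warning leverage 3p/n.
#' @slot residualLimit half-width of the response-domain band (3).
#' @slot p number of model terms including the intercept.
#' @slot nTrain training-set size.
#' @seealso [applicabilityDomain()], [plotWilliams()]
#' @export
setClass("AdReport",
  slots = c(table = "data.frame", hStar = "numeric",
            residualLimit = "numeric", p = "integer", nTrain = "integer"))

#' GAConfig: genetic-algorithm settings for descriptor selection
#'
#' Fixed-length chromosomes (descriptor subsets of size `equationLength`)
#' evolve for `generations` generations: the best `survivors` chromosomes
#' survive unchanged (elitism) and parent the next population of size
#' `populationInit` through single-point crossover (probability
#' `crossoverProb`) and per-gene replacement mutation (probability
#' `mutationProb`).
#'
#' @slot generations,equationLength,populationInit,survivors integers.
#' @slot crossoverProb,mutationProb probabilities between 0 and 1.
#' @slot seed integer RNG seed making a run reproducible.
#' @seealso [gaConfig()], [gaSelect()]
#' @export
setClass("GAConfig",
  slots = c(generations = "integer", equationLength = "integer",
            crossoverProb = "numeric", mutationProb = "numeric",
            populationInit = "integer", survivors = "integer",
            seed = "integer"))

setValidity("GAConfig", function(object) {
  msg <- character()
  if (object@generations < 1L) msg <- c(msg, "generations must be >= 1")
  if (object@equationLength < 1L) msg <- c(msg, "equationLength must be >= 1")
  if (object@populationInit < 2L) msg <- c(msg, "populationInit must be >= 2")
  if (object@survivors < 1L || object@survivors > object@populationInit)
    msg <- c(msg, "survivors must be in [1, populationInit]")
  for (p in c("crossoverProb", "mutationProb"))
    if (slot(object, p) < 0 || slot(object, p) > 1)
      msg <- c(msg, sprintf("%s must be in [0, 1]", p))
  if (length(msg)) msg else TRUE
})

#' Genetic-algorithm configuration
#'
#' Defaults are the selection settings used throughout this package's
#' reference workflow: 1000 generations, 8 descriptors per equation,
#' crossover probability 1, mutation probability 0.5, 100 equations per
#' generation, 3 elitist survivors.
#'
#' @param generations number of GA generations (>= 1).
#' @param equationLength number of descriptors per model.
#' @param crossoverProb probability a child is produced by crossover.
#' @param mutationProb per-gene replacement mutation probability.
#' @param populationInit population size per generation.
#' @param survivors elitist survivors per generation.
#' @param seed integer RNG seed.
#' @return A [GAConfig-class] object.
#' @examples
#' gaConfig(generations = 200, seed = 1)
#' @export
gaConfig <- function(generations = 1000L, equationLength = 8L,
                     crossoverProb = 1, mutationProb = 0.5,
                     populationInit = 100L, survivors = 3L, seed = 1L) {
  new("GAConfig", generations = as.integer(generations),
      equationLength = as.integer(equationLength),
      crossoverProb = crossoverProb, mutationProb = mutationProb,
      populationInit = as.integer(populationInit),
      survivors = as.integer(survivors), seed = as.integer(seed))
}
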