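#' @describeIn QsarDataset-class compound identifiers
#' @param object,x a `QsarDataset`
#' @export
setGeneric("compoundIds", function(object) standardGeneric("compoundIds"))

#' @export
setMethod("compoundIds", "QsarDataset", function(object) object@compounds)

#' @describeIn QsarDataset-class descriptor (column) names
#' @export
setGeneric("descriptorNames",
           function(object) standardGeneric("descriptorNames"))

#' @export
setMethod("descriptorNames", "QsarDataset",
          function(object) colnames(object@X))

#' @describeIn QsarDataset-class descriptor matrix (compounds x descriptors)
#' @export
setGeneric("descriptorMatrix",
           function(object) standardGeneric("descriptorMatrix"))

#' @export
setMethod("descriptorMatrix", "QsarDataset", function(object) object@X)

#' @describeIn QsarDataset-class pIC50 activity vector
#' @export
setGeneric("activity", function(object) standardGeneric("activity"))

#' @export
setMethod("activity", "QsarDataset", function(object) object@y)

#' @describeIn QsarDataset-class `c(n compounds, m descriptors)`
#' @export
setMethod("dim", "QsarDataset", function(x) dim(x@X))

#' Subset a QsarDataset by compounds and/or descriptors
#'
#' @param x a `QsarDataset`
#' @param i compound selector (index, logical or id)
#' @param j descriptor selector (index, logical or name)
#' @param ... ignored
#' @param drop ignored; a `QsarDataset` is always returned
#' @export
setMethod("[", "QsarDataset", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x@compounds)
  if (is.character(i)) i <- match(i, x@compounds)
  if (anyNA(i)) stop("unknown compound id(s) in subset")
  if (missing(j)) j <- seq_len(ncol(x@X))
  new("QsarDataset", compounds = x@compounds[i],
      X = x@X[i, j, drop = FALSE], y = x@y[i])
})

setMethod("show", "QsarDataset", function(object) {
  cat(sprintf("QsarDataset: %d compounds x %d descriptors\n",
              nrow(object@X), ncol(object@X)))
  if (length(object@y))
    cat(sprintf("  pIC50 range: [%.3g, %.3g]\n",
                min(object@y), max(object@y)))
  dn <- colnames(object@X)
  if (!is.null(dn))
    cat("  descriptors: ", paste(utils::head(dn, 5), collapse = ", "),
        if (length(dn) > 5) ", ..." else "", "\n", sep = "")
})

#' @describeIn MlrModel-class named coefficient vector (without intercept)
#' @param object an `MlrModel`
#' @param ... ignored
#' @export
setMethod("coef", "MlrModel", function(object, ...) object@coefficients)

#' @describeIn MlrModel-class names of the model descriptors
#' @export
setMethod("descriptorNames", "MlrModel",
          function(object) names(object@coefficients))

setMethod("show", "MlrModel", function(object) {
  cf <- object@coefficients
  cat(sprintf("MlrModel with %d descriptors%s\n", length(cf),
              if (length(object@scaling)) " (autoscaled)" else ""))
  cat(sprintf("  pIC50 = %.4g +/- %.3g", object@intercept,
              object@interceptSE))
  for (i in seq_along(cf))
    cat(sprintf(" %s %.4g +/- %.3g %s", if (cf[i] < 0) "-" else "+",
                abs(cf[i]), object@coefSE[i], names(cf)[i]))
  cat("\n")
  if (length(object@training))
    cat(sprintf("  trained on n = %d, pIC50 in [%.3g, %.3g]\n",
                object@training$n, object@training$yRange[1],
                object@training$yRange[2]))
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport\n")
  if (length(object@internal)) {
    cat("  internal:\n")
    print(round(object@internal, 4))
  }
  if (length(object@external)) {
    cat("  external:\n")
    print(round(object@external, 4))
  }
  if (!is.na(object@maeVerdict))
    cat("  MAE-based model quality:", object@maeVerdict, "\n")
  if (nrow(object@gtChecks)) {
    cat("  Golbraikh-Tropsha criteria:\n")
    print(object@gtChecks, row.names = FALSE)
  }
})

setMethod("show", "AdReport", function(object) {
  tab <- object@table
  cat(sprintf(
    "AdReport: h* = %.4f (p = %d, n = %d), residual limit +/- %g\n",
    object@hStar, object@p, object@nTrain, object@residualLimit))
  for (s in unique(tab$set))
    cat(sprintf("  %s: %d/%d in domain\n", s,
                sum(tab$inDomain[tab$set == s]), sum(tab$set == s)))
})

setMethod("show", "GAConfig", function(object) {
  cat(sprintf(paste0(
    "GAConfig: %d generations, equation length %d, population %d,\n",
    "  %d survivors, crossover %.2f, per-gene mutation %.2f, seed %d\n"),
    object@generations, object@equationLength, object@populationInit,
    object@survivors, object@crossoverProb, object@mutationProb,
    object@seed))
})
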