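#' Apply a fitted model to descriptor vectors
#'
#' Applies the model's stored scaling (if any) and linear form to named
#' descriptor values. Every model descriptor must be present; extra
#' descriptors are ignored with a warning. Predictions outside the
#' model's training activity range are flagged with an extrapolation
#' warning but returned unchanged.
#'
#' @param model an [MlrModel-class].
#' @param descriptors a named numeric vector (one compound), a
#'   data.frame/matrix with descriptor columns, or a
#'   [QsarDataset-class].
#' @param warnExtrapolation warn when predictions leave the training
#'   activity range.
#' @param warnExtra warn about descriptors present in the input but not
#'   in the model (they are always ignored).
#' @return numeric vector of predicted pIC50 values.
#' @examples
#' m <- publishedModel("PTP1B")
#' applyModel(m, setNames(rep(0, 8), descriptorNames(m)))  # = intercept
#' @export
applyModel <- function(model, descriptors, warnExtrapolation = TRUE,
                       warnExtra = TRUE) {
  need <- names(model@coefficients)
  if (is(descriptors, "QsarDataset"))
    descriptors <- descriptorMatrix(descriptors)
  if (is.numeric(descriptors) && is.null(dim(descriptors)))
    descriptors <- matrix(descriptors, nrow = 1,
                          dimnames = list(NULL, names(descriptors)))
  descriptors <- as.matrix(as.data.frame(descriptors,
                                         check.names = FALSE))
  miss <- setdiff(need, colnames(descriptors))
  if (length(miss))
    stop("missing model descriptor(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(colnames(descriptors), need)
  if (warnExtra && length(extra))
    warning("ignoring descriptor(s) not in the model: ",
            paste(extra, collapse = ", "))
  X <- descriptors[, need, drop = FALSE]
  storage.mode(X) <- "double"
  if (length(model@scaling))
    X <- scale(X, center = model@scaling$center[need],
               scale = model@scaling$scale[need])
  pred <- drop(X %*% model@coefficients) + model@intercept
  rng <- model@training$yRange
  if (warnExtrapolation && length(rng) == 2 && all(is.finite(rng)) &&
      any(pred < rng[1] | pred > rng[2]))
    warning("prediction(s) outside the training activity range [",
            signif(rng[1], 4), ", ", signif(rng[2], 4),
            "] (extrapolation)")
  unname(pred)
}

#' @describeIn applyModel standard `predict` interface
#' @param object an [MlrModel-class]
#' @param newdata descriptor input as for `applyModel`
#' @param ... passed to `applyModel`
#' @export
setMethod("predict", "MlrModel", function(object, newdata, ...)
  applyModel(object, newdata, ...))

#' Activity unit conversions
#'
#' `pic50ToMolar` returns the molar IC50 `10^(-pIC50)` (mol/dm3);
#' `molarToPic50` is its inverse. `molarToMassConc` converts a molar
#' concentration to ug/ml via the molar mass
#' (`mol/L * g/mol = g/L = 1000 ug/ml`); `massConcToMolar` inverts it.
#'
#' @param pic50 pIC50 values (-log10 molar IC50).
#' @param ic50Molar molar concentration (mol/dm3).
#' @param massConc mass concentration (ug/ml).
#' @param mw molar mass (g/mol, > 0).
#' @return numeric vector in the target unit.
#' @examples
#' pic50ToMolar(6)                      # 1e-6 mol/dm3
#' molarToMassConc(1e-6, mw = 1000)    # 1 ug/ml
#' @export
pic50ToMolar <- function(pic50) {
  stopifnot(all(is.finite(pic50)))
  10^(-pic50)
}

#' @rdname pic50ToMolar
#' @export
molarToPic50 <- function(ic50Molar) {
  stopifnot(all(ic50Molar > 0))
  -log10(ic50Molar)
}

#' @rdname pic50ToMolar
#' @export
molarToMassConc <- function(ic50Molar, mw) {
  if (any(!is.na(mw) & mw <= 0)) stop("mw must be positive")
  ic50Molar * mw * 1000
}

#' @rdname pic50ToMolar
#' @export
massConcToMolar <- function(massConc, mw) {
  if (any(!is.na(mw) & mw <= 0)) stop("mw must be positive")
  massConc / (mw * 1000)
}

#' Prediction table in all three activity units
#'
#' One row per compound: predicted pIC50, molar IC50 and mass IC50
#' (ug/ml, when a molar mass is available). With `rounded = TRUE` the
#' molar column is rounded to 3 significant figures and the mass column
#' to 2 decimal places (the conventional printed style); full precision
#' otherwise.
#'
#' @param model an [MlrModel-class].
#' @param compounds data.frame with an id column, the model's descriptor
#'   columns, and optionally a molar-mass column.
#' @param idColumn,mwColumn column names for identifiers and molar mass
#'   (g/mol). `mwColumn = NULL`, or NA entries, leave the mass column NA
#'   (flagged in the `massAvailable` column).
#' @param rounded apply the printed-style rounding rule.
#' @return data.frame: id, pic50, ic50_molar, mw, ic50_ugml,
#'   massAvailable.
#' @export
predictionTable <- function(model, compounds, idColumn = "name",
                            mwColumn = "mw", rounded = FALSE) {
  if (!nrow(compounds)) {
    return(data.frame(id = character(), pic50 = numeric(),
                      ic50_molar = numeric(), mw = numeric(),
                      ic50_ugml = numeric(), massAvailable = logical()))
  }
  pic50 <- applyModel(model, compounds[setdiff(names(compounds),
                                               c(idColumn, mwColumn))],
                      warnExtrapolation = FALSE)
  molar <- pic50ToMolar(pic50)
  mw <- if (!is.null(mwColumn) && mwColumn %in% names(compounds))
    as.numeric(compounds[[mwColumn]]) else rep(NA_real_, nrow(compounds))
  mass <- ifelse(is.na(mw), NA_real_, molarToMassConc(molar, mw))
  if (rounded) {
    molar <- signif(molar, 3)
    mass <- round(mass, 2)
  }
  data.frame(id = if (idColumn %in% names(compounds))
               compounds[[idColumn]] else seq_len(nrow(compounds)),
             pic50 = pic50, ic50_molar = molar, mw = mw,
             ic50_ugml = mass, massAvailable = !is.na(mw))
}
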