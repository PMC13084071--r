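## CSV / JSON plumbing shared by all stages. All readers normalize the
## typographic minus (U+2212) to ASCII before numeric parsing, and accept
## "a +/- b" spread notation (either U+00B1 or "+/-").

normalizeMinus <- function(x) gsub("\u2212", "-", x)

#' Parse "value +/- spread" notation
#'
#' Accepts `"a +/- b"` or a bare number, where the separator may be the
#' plus-minus sign U+00B1 or the ASCII `+/-`; the typographic minus
#' U+2212 is accepted anywhere. The spread is `NA` when absent.
#'
#' @param x character vector.
#' @return data.frame with columns `value` and `spread`.
#' @examples
#' parseSpread(c("-44.05 +/- 7.74", "1.5", "2 +/- 0.1"))
#' @export
parseSpread <- function(x) {
  x <- normalizeMinus(trimws(as.character(x)))
  parts <- strsplit(x, "\u00b1|\\+/-")
  value <- vapply(parts, function(p) as.numeric(trimws(p[1])), numeric(1))
  spread <- vapply(parts, function(p)
    if (length(p) > 1) as.numeric(trimws(p[2])) else NA_real_, numeric(1))
  data.frame(value = value, spread = spread)
}

#' Read a QSAR descriptor table from CSV
#'
#' Expects a header row, one identifier column, numeric descriptor columns
#' and one activity (pIC50) column. Column order is preserved. Cells that
#' cannot be parsed as numbers become `NA` and are reported in a warning
#' (they are what [preprocessDescriptors()] later removes).
#'
#' @param path CSV file path (RFC-4180, UTF-8).
#' @param activityColumn name of the pIC50 column.
#' @param idColumn name of the identifier column; by default the first
#'   column is used.
#' @return A [QsarDataset-class].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(id = c("a", "b", "c"), D1 = 1:3, D2 = c(2, 1, 0),
#'                      pIC50 = c(5, 6, 7)), tf, row.names = FALSE)
#' readQsarCsv(tf, "pIC50")
#' @export
readQsarCsv <- function(path, activityColumn = "pIC50", idColumn = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (is.null(idColumn)) idColumn <- names(raw)[1]
  if (!idColumn %in% names(raw))
    stop("id column '", idColumn, "' not found in ", path)
  if (!activityColumn %in% names(raw))
    stop("activity column '", activityColumn, "' not found in ", path,
         " (configuration error)")
  ids <- raw[[idColumn]]
  if (anyDuplicated(ids))
    stop("duplicate compound ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  descCols <- setdiff(names(raw), c(idColumn, activityColumn))
  X <- vapply(raw[descCols], function(col)
    suppressWarnings(as.numeric(normalizeMinus(col))),
    numeric(nrow(raw)))
  X <- matrix(X, nrow = nrow(raw),
              dimnames = list(NULL, descCols))
  bad <- colSums(is.na(X) & !(trimws(as.matrix(raw[descCols])) %in%
                                c("", "NA", "na", "NaN")))
  if (any(bad > 0))
    warning("unparseable numeric values in column(s): ",
            paste(sprintf("%s (%d)", names(bad)[bad > 0], bad[bad > 0]),
                  collapse = ", "))
  y <- suppressWarnings(as.numeric(normalizeMinus(raw[[activityColumn]])))
  if (anyNA(y) || !all(is.finite(y)))
    stop("activity column '", activityColumn,
         "' contains missing or non-finite values")
  qsarDataset(X, y, compounds = ids)
}

#' Write a QsarDataset to CSV
#'
#' Writes the dialect [readQsarCsv()] reads; values round-trip at full
#' double precision (15 significant digits).
#'
#' @param dataset a [QsarDataset-class].
#' @param path output file.
#' @param activityColumn name for the activity column.
#' @return `path`, invisibly.
#' @export
writeQsarCsv <- function(dataset, path, activityColumn = "pIC50") {
  df <- data.frame(id = compoundIds(dataset), check.names = FALSE)
  X <- descriptorMatrix(dataset)
  for (j in colnames(X)) df[[j]] <- format(X[, j], digits = 15, trim = TRUE)
  df[[activityColumn]] <- format(activity(dataset), digits = 15, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / deserialize an MlrModel as JSON
#'
#' The JSON layout is `{intercept, intercept_se,
#' coefficients:[{name,value,se}], scaling, training:{n,y_min,y_max}}`;
#' `scaling` is `null` for unscaled models. `readModelJson(writeModelJson(m))`
#' is the identity field-for-field.
#'
#' @param model an [MlrModel-class].
#' @param path JSON file path.
#' @return `writeModelJson`: `path` invisibly; `readModelJson`: the model.
#' @export
writeModelJson <- function(model, path) {
  stopifnot(is(model, "MlrModel"))
  validObject(model)
  obj <- list(
    intercept = model@intercept,
    intercept_se = model@interceptSE,
    coefficients = lapply(seq_along(model@coefficients), function(i)
      list(name = names(model@coefficients)[i],
           value = unname(model@coefficients[i]),
           se = unname(model@coefSE[i]))),
    scaling = if (length(model@scaling))
      list(center = as.list(model@scaling$center),
           scale = as.list(model@scaling$scale)) else NULL,
    training = if (length(model@training))
      list(n = model@training$n,
           y_min = model@training$yRange[1],
           y_max = model@training$yRange[2]) else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname writeModelJson
#' @export
readModelJson <- function(path) {
  obj <- jsonlite::read_json(path)
  need <- c("intercept", "intercept_se", "coefficients")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("malformed model file ", path, ": missing key(s) ",
         paste(miss, collapse = ", "))
  if (!length(obj$coefficients))
    stop("malformed model file ", path, ": empty 'coefficients'")
  cf <- vapply(obj$coefficients, function(e) {
    if (is.null(e$name) || is.null(e$value))
      stop("malformed model file ", path,
           ": coefficient entry lacks 'name' or 'value'")
    as.numeric(e$value)
  }, numeric(1))
  names(cf) <- vapply(obj$coefficients, function(e) e$name, character(1))
  se <- vapply(obj$coefficients, function(e)
    if (is.null(e$se)) NA_real_ else as.numeric(e$se), numeric(1))
  names(se) <- names(cf)
  scaling <- list()
  if (!is.null(obj$scaling)) {
    scaling <- list(center = unlist(obj$scaling$center),
                    scale = unlist(obj$scaling$scale))
  }
  training <- list()
  if (!is.null(obj$training)) {
    num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
    training <- list(n = as.integer(num(obj$training$n)),
                     yRange = c(num(obj$training$y_min),
                                num(obj$training$y_max)))
  }
  new("MlrModel", intercept = as.numeric(obj$intercept),
      interceptSE = as.numeric(obj$intercept_se),
      coefficients = cf, coefSE = se, scaling = scaling,
      training = training)
}

fixturePath <- function(file)
  system.file("extdata", file, package = "phytoQSAR", mustWork = TRUE)

## tolerance used only to flag printed-inconsistency rows at load time;
## half-unit rounding of the mixed 1-dp/2-dp subtotals can accumulate to
## ~0.06, so anything beyond 0.1 is a genuine misprint, not rounding.
.flagTol <- 0.1

#' Load a packaged published-table fixture
#'
#' Returns the in-package copies of the published reference tables exactly
#' as printed (typographic minus normalized to ASCII), typed per row:
#' \describe{
#'   \item{`table2`}{MM-GBSA energy components: data.frame with `value` and
#'     `spread` columns per term plus a `flagInconsistent` column marking
#'     rows whose printed subtotals violate the thermodynamic cycle beyond
#'     printed-rounding tolerance (0.1 kcal/mol).}
#'   \item{`table3`}{`list(parameters=, correlations=list(PTP1B=, DPP4=))`
#'     of post-dynamics descriptors and their correlation matrices.}
#'   \item{`table4`}{`list(profiles=, correlations=...)`: conceptual-DFT
#'     reactivity descriptors with binding energies; rows whose printed
#'     derived descriptors contradict the defining formulas (the
#'     column-shifted sitagliptin row; rutin's electrophilicity) carry
#'     `flagInconsistent = TRUE`.}
#'   \item{`table7`}{long-format validation-parameter table for both
#'     published QSAR models.}
#'   \item{`table8`}{descriptor values, predicted pIC50 and converted IC50
#'     (molar and ug/ml) for the lead compounds.}
#' }
#' Inconsistent rows are loaded verbatim with a warning, never corrected.
#'
#' @param name one of `"table2"`, `"table3"`, `"table4"`, `"table7"`,
#'   `"table8"`.
#' @return A data.frame or list as described above.
#' @export
loadFixture <- function(name) {
  known <- c("table2", "table3", "table4", "table7", "table8")
  if (!is.character(name) || length(name) != 1 || !name %in% known)
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  switch(name,
    table2 = loadTable2(),
    table3 = loadTable3(),
    table4 = loadTable4(),
    table7 = utils::read.csv(fixturePath("table7_validation.csv"),
                             check.names = FALSE),
    table8 = utils::read.csv(fixturePath("table8_predictions.csv"),
                             check.names = FALSE))
}

loadTable2 <- function() {
  raw <- utils::read.csv(fixturePath("table2_mmgbsa.csv"),
                         colClasses = "character", fileEncoding = "UTF-8")
  terms <- c("e_vdw", "e_elec", "e_gb", "e_surf", "g_gas", "g_solv",
             "g_bind")
  out <- data.frame(target = raw$target, complex = raw$complex)
  for (t in terms) {
    p <- parseSpread(raw[[t]])
    out[[t]] <- p$value
    out[[paste0(t, "_spread")]] <- p$spread
  }
  res <- cycleResiduals(out)
  out$flagInconsistent <- apply(abs(res), 1, max) > .flagTol
  if (any(out$flagInconsistent))
    warning("printed-inconsistency row(s) in table2 (loaded verbatim): ",
            paste(out$complex[out$flagInconsistent], collapse = ", "))
  attr(out, "units") <- "kcal/mol"
  out
}

loadTable3 <- function() {
  raw <- utils::read.csv(fixturePath("table3_postdyn.csv"),
                         colClasses = "character", fileEncoding = "UTF-8")
  out <- data.frame(target = raw$target, complex = raw$complex)
  for (t in c("rmsd", "rog", "rmsf", "sasa", "n_hbond")) {
    p <- parseSpread(raw[[t]])
    out[[t]] <- p$value
    out[[paste0(t, "_spread")]] <- p$spread
  }
  corr <- utils::read.csv(fixturePath("table3_correlations.csv"),
                          check.names = FALSE)
  mats <- lapply(split(corr, corr$target), function(block) {
    m <- as.matrix(block[, -(1:2)])
    rownames(m) <- block$parameter
    m[upper.tri(m)] <- t(m)[upper.tri(m)]   # printed lower triangle
    m
  })
  list(parameters = out, correlations = mats[c("PTP1B", "DPP4")])
}

loadTable4 <- function() {
  prof <- utils::read.csv(fixturePath("table4_reactivity.csv"),
                          check.names = FALSE)
  ## flag rows whose printed derived descriptors contradict the defining
  ## formulas at > 0.02 (printed 2-dp half-unit plus rounding headroom)
  ip <- -prof$homo; ea <- -prof$lumo
  eta <- (ip - ea) / 2; chi <- (ip + ea) / 2
  bad <- abs(prof$delta_e - (prof$lumo - prof$homo)) > 0.02 |
    abs(prof$eta - eta) > 0.02 | abs(prof$chi - chi) > 0.02 |
    abs(prof$mu + chi) > 0.02 |
    abs(prof$omega - chi^2 / (2 * eta)) > 0.02 |
    abs(prof$xi - 1 / eta) > 0.02
  prof$flagInconsistent <- bad
  if (any(bad))
    warning("printed-inconsistency row(s) in table4 (loaded verbatim): ",
            paste(paste(prof$target[bad], prof$compound[bad], sep = "/"),
                  collapse = ", "))
  corr <- utils::read.csv(fixturePath("table4_correlations.csv"),
                          check.names = FALSE)
  m <- as.matrix(corr[, -1])
  rownames(m) <- corr$parameter
  ## single printed matrix: lower triangle is the PTP1B block, upper
  ## triangle the DPP4 block; split into two full symmetric matrices
  ptp1b <- m; ptp1b[upper.tri(ptp1b)] <- t(ptp1b)[upper.tri(ptp1b)]
  dpp4 <- m; dpp4[lower.tri(dpp4)] <- t(dpp4)[lower.tri(dpp4)]
  list(profiles = prof,
       correlations = list(PTP1B = ptp1b, DPP4 = dpp4))
}

#' Published QSAR models
#'
#' The two published GA-MLR equations as ready-to-use [MlrModel-class]
#' objects: the PTP1B model (8 descriptors, intercept 6.697, trained on
#' 330 compounds) and the DPP4 model (8 descriptors, intercept -5.494,
#' trained on 91 compounds). Coefficients are reported with their printed
#' standard errors. Note these models embed an undisclosed descriptor
#' scaling on the original software's side, so applying them to raw
#' PaDEL-style descriptor values does not reproduce the published
#' predictions (see the package vignette).
#'
#' @param target `"PTP1B"` or `"DPP4"`.
#' @return An [MlrModel-class].
#' @examples
#' publishedModel("PTP1B")
#' @export
publishedModel <- function(target = c("PTP1B", "DPP4")) {
  target <- match.arg(target)
  if (target == "PTP1B") {
    cf <- c(R_TpiPCTPC = 0.927, nRing = -2.007, ATSC4m = 0.743,
            GATS3p = -0.767, fragC = 3.407, MATS7e = -0.267,
            MAXDP = -1.308, AATS3e = -0.756)
    se <- c(R_TpiPCTPC = 0.070, nRing = 0.177, ATSC4m = 0.146,
            GATS3p = 0.086, fragC = 0.188, MATS7e = 0.105,
            MAXDP = 0.118, AATS3e = 0.089)
    new("MlrModel", intercept = 6.697, interceptSE = 0.111,
        coefficients = cf, coefSE = se, scaling = list(),
        training = list(n = 330L, yRange = c(NA_real_, NA_real_)))
  } else {
    cf <- c(SIC0 = -2.521, GATS7m = 2.015, SpMax1_Bhv = 6.098,
            JGT = 3.804, apol = 0.044, SpMin2_Bhv = -9.424,
            ATSC6p = 0.119, AATSC8p = 10.345)
    se <- c(SIC0 = 0.952, GATS7m = 0.174, SpMax1_Bhv = 0.256,
            JGT = 0.428, apol = 0.003, SpMin2_Bhv = 0.382,
            ATSC6p = 0.010, AATSC8p = 0.592)
    new("MlrModel", intercept = -5.494, interceptSE = 0.816,
        coefficients = cf, coefSE = se, scaling = list(),
        training = list(n = 91L, yRange = c(NA_real_, NA_real_)))
  }
}
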