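#' Conceptual-DFT global reactivity descriptors
#'
#' Derives the eight global reactivity descriptors from frontier orbital
#' energies (Koopmans-type finite-difference approximations):
#' \itemize{
#'   \item energy gap `delta_e = lumo - homo`
#'   \item ionization potential `ip = -homo`, electron affinity
#'     `ea = -lumo`
#'   \item chemical hardness `eta = (ip - ea)/2`, electronegativity
#'     `chi = (ip + ea)/2`, chemical potential `mu = -chi`
#'   \item softness `xi`: `1/eta` (default) or `1/(2*eta)` depending on
#'     `softnessConvention` — both conventions circulate in the
#'     literature, and published tables frequently print `1/eta` next to
#'     a `1/(2*eta)` formula, so the choice is explicit here
#'   \item electrophilicity index `omega = mu^2 / (2*eta)`
#' }
#' All inputs and outputs are in eV (`xi` in eV^-1). When `homo >= lumo`
#' the profile is still computed, with a warning (hardness is then
#' non-positive); when `eta == 0`, `xi` and `omega` are `NaN` and flagged.
#'
#' @param homo,lumo orbital energies in eV (vectorized).
#' @param softnessConvention `"inverse_eta"` or `"inverse_2eta"`.
#' @param compound optional identifiers for the output rows.
#' @return data.frame with columns homo, lumo, delta_e, ip, ea, eta, xi,
#'   chi, mu, omega (one row per compound).
#' @examples
#' reactivityProfile(homo = -5.80, lumo = -1.66)
#' @export
reactivityProfile <- function(homo, lumo,
                              softnessConvention = c("inverse_eta",
                                                     "inverse_2eta"),
                              compound = NULL) {
  softnessConvention <- match.arg(softnessConvention)
  stopifnot(length(homo) == length(lumo))
  if (any(homo >= lumo))
    warning("homo >= lumo for some compound(s); ",
            "hardness is non-positive and derived descriptors suspect")
  ip <- -homo
  ea <- -lumo
  eta <- (ip - ea) / 2
  chi <- (ip + ea) / 2
  mu <- -chi
  xi <- if (softnessConvention == "inverse_eta") 1 / eta else 1 / (2 * eta)
  omega <- mu^2 / (2 * eta)
  if (any(eta == 0))
    warning("eta == 0 for some compound(s); xi and omega undefined")
  out <- data.frame(homo = homo, lumo = lumo, delta_e = lumo - homo,
                    ip = ip, ea = ea, eta = eta, xi = xi, chi = chi,
                    mu = mu, omega = omega)
  if (!is.null(compound)) out <- cbind(compound = compound, out)
  out
}

#' Pairwise Pearson correlation matrix
#'
#' Symmetric matrix of pairwise Pearson correlations over named numeric
#' vectors (or the columns of a data.frame/matrix). Pairs are computed on
#' complete observations; full precision is retained — round only for
#' reporting. Zero-variance columns yield `NA` correlations with a
#' warning rather than an error.
#'
#' @param columns named list of numeric vectors, data.frame, or matrix.
#' @param minComplete minimum complete rows required per pair.
#' @return symmetric numeric matrix with unit diagonal.
#' @examples
#' correlationMatrix(list(a = 1:5, b = c(2, 4, 5, 4, 5)))
#' @export
correlationMatrix <- function(columns, minComplete = 3) {
  m <- as.matrix(as.data.frame(columns, check.names = FALSE))
  if (!is.numeric(m)) stop("all columns must be numeric")
  nOk <- crossprod(!is.na(m))
  if (any(nOk < minComplete))
    stop("fewer than ", minComplete, " complete rows for some pair(s)")
  zv <- apply(m, 2, function(col) stats::var(col, na.rm = TRUE) == 0)
  if (any(zv))
    warning("zero-variance column(s): ",
            paste(colnames(m)[zv], collapse = ", "),
            "; their correlations are undefined (NA)")
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(r) <- ifelse(zv, NA_real_, 1)
  r
}
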