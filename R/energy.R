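## MM-GBSA bookkeeping. The thermodynamic cycle behind every row:
##   dG_gas  = dE_vdW + dE_elec
##   dG_solv = dE_GB  + dE_surf
##   dG_bind = dG_gas + dG_solv
## (entropy terms are out of scope: the upstream protocol omits -TdS).

cycleResiduals <- function(row) {
  cbind(gas  = row$g_gas - (row$e_vdw + row$e_elec),
        solv = row$g_solv - (row$e_gb + row$e_surf),
        bind = row$g_bind - (row$g_gas + row$g_solv))
}

#' Validate the MM-GBSA thermodynamic cycle
#'
#' Checks the three component identities (gas = vdW + elec,
#' solv = GB + surf, bind = gas + solv) on one or more energy rows.
#' Reported "+/-" spreads, when present, are carried along but play no role
#' in the residuals.
#'
#' @param rows data.frame with columns `e_vdw`, `e_elec`, `e_gb`,
#'   `e_surf`, `g_gas`, `g_solv`, `g_bind` (kcal/mol), e.g. one or more
#'   rows of `loadFixture("table2")` or [genEnergyTable()].
#' @param tolerance maximum absolute residual (kcal/mol). The default
#'   0.02 suits tables printed to 2 decimal places; use ~1e-9 for
#'   machine-precision inputs.
#' @return data.frame with the three residuals, a per-identity pass flag
#'   and an overall `pass` column.
#' @examples
#' tab <- suppressWarnings(loadFixture("table2"))
#' validateThermoCycle(tab[1, ])
#' @export
validateThermoCycle <- function(rows, tolerance = 0.02) {
  need <- c("e_vdw", "e_elec", "e_gb", "e_surf", "g_gas", "g_solv",
            "g_bind")
  miss <- setdiff(need, names(rows))
  if (length(miss))
    stop("missing energy component(s): ", paste(miss, collapse = ", "))
  if (anyNA(rows[need]))
    stop("missing (NA) energy component values")
  res <- cycleResiduals(rows)
  out <- data.frame(
    complex = if ("complex" %in% names(rows)) rows$complex
              else seq_len(nrow(rows)),
    residual_gas = res[, "gas"], residual_solv = res[, "solv"],
    residual_bind = res[, "bind"],
    pass_gas = abs(res[, "gas"]) <= tolerance,
    pass_solv = abs(res[, "solv"]) <= tolerance,
    pass_bind = abs(res[, "bind"]) <= tolerance)
  out$pass <- out$pass_gas & out$pass_solv & out$pass_bind
  out
}

#' Aggregate MM-GBSA components into the cycle sums
#'
#' @param e_vdw,e_elec,e_gb,e_surf numeric vectors (kcal/mol).
#' @return data.frame with `g_gas`, `g_solv`, `g_bind`; by construction
#'   these satisfy [validateThermoCycle()] with tolerance 0.
#' @examples
#' aggregateComponents(-44.05, -94.84, 93.93, -7.22)
#' @export
aggregateComponents <- function(e_vdw, e_elec, e_gb, e_surf) {
  stopifnot(all(is.finite(c(e_vdw, e_elec, e_gb, e_surf))))
  g_gas <- e_vdw + e_elec
  g_solv <- e_gb + e_surf
  data.frame(g_gas = g_gas, g_solv = g_solv, g_bind = g_gas + g_solv)
}

#' Rank per-residue energy contributions
#'
#' Sorts a per-residue decomposition ascending by energy (most favorable,
#' i.e. most negative, first); ties are broken by residue number parsed
#' from the identifier (e.g. `"Glu206"` -> 206), then by identifier.
#'
#' @param decomposition data.frame with columns `residue` and `energy`
#'   (kcal/mol), or a named numeric vector.
#' @param top_k number of residues to return; values larger than the list
#'   return the whole ranking.
#' @return data.frame of the `top_k` most favorable contributions.
#' @examples
#' rankResidueContributions(
#'   c(Glu206 = -8.49, Tyr547 = -3.06, Ser630 = -0.59), top_k = 1)
#' @export
rankResidueContributions <- function(decomposition, top_k = nrow(df)) {
  if (is.numeric(decomposition) && !is.null(names(decomposition)))
    decomposition <- data.frame(residue = names(decomposition),
                                energy = unname(decomposition))
  df <- decomposition
  if (!nrow(df)) stop("empty decomposition")
  if (missing(top_k)) top_k <- nrow(df)
  if (top_k <= 0) stop("top_k must be positive")
  resnum <- suppressWarnings(as.numeric(gsub("\\D", "", df$residue)))
  ord <- order(df$energy, resnum, df$residue)
  utils::head(df[ord, , drop = FALSE], top_k)
}

#' Correlate binding free energies with post-dynamics descriptors
#'
#' Pearson correlation of dG_bind with each trajectory-summary descriptor
#' (RMSD, ROG, RMSF, SASA, hydrogen-bond count), matched by complex id.
#'
#' @param energies data.frame with columns `complex` and `g_bind`, or a
#'   named numeric vector of binding energies.
#' @param records data.frame of post-dynamics descriptors with a
#'   `complex` column (e.g. `loadFixture("table3")$parameters`).
#' @param columns descriptor columns to correlate; defaults to every
#'   numeric non-spread column of `records`.
#' @return named numeric vector of correlations.
#' @export
correlatePostDynamics <- function(energies, records, columns = NULL) {
  if (is.numeric(energies) && !is.null(names(energies)))
    energies <- data.frame(complex = names(energies),
                           g_bind = unname(energies))
  unmatched <- setdiff(energies$complex, records$complex)
  if (length(unmatched))
    stop("complex id(s) without post-dynamics records: ",
         paste(unmatched, collapse = ", "))
  if (nrow(energies) < 3)
    stop("need at least 3 complexes to correlate")
  rec <- records[match(energies$complex, records$complex), ]
  if (is.null(columns)) {
    columns <- setdiff(names(rec)[vapply(rec, is.numeric, logical(1))],
                       c("g_bind", grep("_spread$", names(rec),
                                        value = TRUE)))
  }
  cols <- c(list(g_bind = energies$g_bind),
            as.list(rec[columns]))
  correlationMatrix(cols)["g_bind", columns]
}
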