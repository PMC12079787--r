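# Reaction-energetics arithmetic and error aggregation. Energies-only:
# works on any model's outputs in a common declared unit.

#' Reaction energetics of a reactant / transition-state / product triple
#'
#' Returns the reaction energy (P-R), barrier height (TS-R) and
#' transition-state-to-product difference (TS-P). The thermodynamic-cycle
#' identity TS-R = P-R + TS-P holds exactly. Vectorized.
#'
#' @param reactant,ts,product energies in a common unit.
#' @return data.frame with columns `p_minus_r`, `ts_minus_r`, `ts_minus_p`.
#' @export
reaction_energetics <- function(reactant, ts, product) {
  stopifnot(length(reactant) == length(ts), length(ts) == length(product))
  data.frame(p_minus_r = product - reactant,
             ts_minus_r = ts - reactant,
             ts_minus_p = ts - product)
}

#' Bond dissociation energy
#'
#' Sum of the product fragment energies minus the intact reactant energy.
#'
#' @param reactant_energy energy of the intact molecule.
#' @param fragment_energies energies of the dissociation products
#'   (at least one).
#' @return scalar BDE in the input unit.
#' @export
bde <- function(reactant_energy, fragment_energies) {
  if (length(fragment_energies) < 1) {
    stop("at least one fragment energy is required", call. = FALSE)
  }
  sum(fragment_energies) - reactant_energy
}

#' Mean-absolute-error report, overall and per group
#'
#' @param pred,ref equal-length numeric vectors.
#' @param groups optional labels partitioning the entries.
#' @return data.frame with columns `group`, `n`, `mae`; the overall row is
#'   labelled `"all"` and comes last.
#' @export
mae_report <- function(pred, ref, groups = NULL) {
  if (length(pred) != length(ref)) {
    stop("pred and ref must have equal length", call. = FALSE)
  }
  err <- abs(pred - ref)
  rows <- NULL
  if (!is.null(groups)) {
    if (length(groups) != length(pred)) {
      stop("groups must match pred/ref length", call. = FALSE)
    }
    rows <- do.call(rbind, lapply(split(err, groups), function(e) {
      data.frame(n = length(e), mae = mean(e))
    }))
    rows <- data.frame(group = rownames(rows), rows, row.names = NULL,
                       stringsAsFactors = FALSE)
  }
  rbind(rows, data.frame(group = "all", n = length(err), mae = mean(err)))
}
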