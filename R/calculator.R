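# Pluggable calculator contract. Any energy/force backend (the bundled toy
# force field, or a wrapper around a real quantum-chemistry code) plugs into
# the sampler through this interface.

#' Construct a calculator
#'
#' A calculator evaluates a geometry and returns a list with `energy`
#' (scalar), `forces` (n x 3 matrix, negative energy gradient), and
#' optionally `dipole` (length 3) and `orbitals`
#' (`list(energies = <spin-orbital energies>, n_electrons = <integer>)`).
#' Evaluation failure must be signalled with [calculator_failure()] — never
#' returned as silent NaN; the sampling loop turns such failures into
#' discarded geometries, mirroring how non-converged quantum-chemistry
#' labels are dropped.
#'
#' @param evaluate function(geometry) returning the list described above.
#' @param capabilities character subset of
#'   `c("energy","forces","dipole","orbital_energies")`.
#' @param units named character vector declaring the unit system; the
#'   package convention is eV / Angstrom / fs / amu.
#' @param label short descriptive name.
#' @return object of class `bb_calculator`.
#' @export
new_calculator <- function(evaluate,
                           capabilities = c("energy", "forces"),
                           units = c(energy = "eV", length = "angstrom"),
                           label = "custom") {
  stopifnot(is.function(evaluate))
  ok <- c("energy", "forces", "dipole", "orbital_energies")
  if (!all(capabilities %in% ok)) {
    stop("unknown capability: ", paste(setdiff(capabilities, ok), collapse = ", "),
         call. = FALSE)
  }
  structure(list(evaluate = evaluate, capabilities = capabilities,
                 units = units, label = label),
            class = "bb_calculator")
}

#' @export
print.bb_calculator <- function(x, ...) {
  cat(sprintf("<bb_calculator> %s [%s]\n", x$label,
              paste(x$capabilities, collapse = ", ")))
  invisible(x)
}

#' Signal a calculator evaluation failure
#'
#' Raises a classed condition (`bb_calc_failure`) that the sampling loop
#' catches to flag the affected geometry as discarded.
#'
#' @param message description of the failure.
#' @export
calculator_failure <- function(message = "calculator evaluation failed") {
  stop(structure(class = c("bb_calc_failure", "error", "condition"),
                 list(message = message, call = NULL)))
}

has_capability <- function(calc, what) what %in% calc$capabilities

#' Evaluate a geometry with a calculator
#'
#' Validates the calculator output: finite energy, correctly shaped finite
#' forces. Failures raised with [calculator_failure()] propagate as classed
#' conditions.
#'
#' @param calc a `bb_calculator`.
#' @param geom a `bb_geometry`.
#' @return the calculator result list.
#' @export
calc_evaluate <- function(calc, geom) {
  res <- calc$evaluate(geom)
  if (!is.finite(res$energy)) calculator_failure("non-finite energy")
  if (has_capability(calc, "forces")) {
    f <- res$forces
    if (is.null(f) || !is.matrix(f) || nrow(f) != n_atoms(geom) ||
        ncol(f) != 3 || !all(is.finite(f))) {
      calculator_failure("invalid or non-finite forces")
    }
  }
  res
}
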