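# Finite-temperature occupation analysis: Fermi-level solving, Fermi-Dirac
# fractional occupation (FO) numbers, and the N_FOD radical-character
# measure computed in occupation space (for orthonormal orbitals the
# real-space fractional-orbital-density integral reduces to the occupation
# sum).

#' Fermi-Dirac occupations of a spin-orbital spectrum
#'
#' Levels are spin orbitals: each holds at most one electron. For
#' `t_el > 0` the Fermi energy is solved by bisection so that the
#' occupations sum to `n_electrons` (to 1e-10). At `t_el = 0` occupations
#' are a step function; degenerate levels at the Fermi cut share the
#' remaining electrons equally, and for a gapped filling the Fermi energy
#' is placed mid-gap.
#'
#' Energies are in eV (the Boltzmann constant used is 8.617333262e-5 eV/K).
#'
#' @param energies numeric vector of spin-orbital energies (eV).
#' @param n_electrons number of electrons (0 <= n <= number of levels).
#' @param t_el electronic temperature (K, >= 0).
#' @return object of class `occupation_result`: list with `fermi_energy`,
#'   `occupations` (aligned with `energies`), `n_electrons`, `t_el`.
#' @export
fermi_occupations <- function(energies, n_electrons, t_el) {
  if (!all(is.finite(energies))) stop("energies must be finite", call. = FALSE)
  if (t_el < 0) stop("t_el must be >= 0", call. = FALSE)
  n_lev <- length(energies)
  if (n_electrons < 0 || n_electrons > n_lev) {
    stop(sprintf("infeasible electron count %s for %d levels",
                 format(n_electrons), n_lev), call. = FALSE)
  }
  if (t_el == 0) {
    ord <- order(energies)
    f <- numeric(n_lev)
    if (n_electrons > 0) {
      e_sorted <- energies[ord]
      e_cut <- e_sorted[n_electrons]
      deg <- abs(energies - e_cut) <= 1e-9
      below <- energies < e_cut - 1e-9
      f[below] <- 1
      rem <- n_electrons - sum(below)
      f[deg] <- rem / sum(deg)
      ef <- if (rem == sum(deg) && n_electrons < n_lev) {
        # gapped filling: mid-gap Fermi energy
        e_lumo <- min(e_sorted[e_sorted > e_cut + 1e-9])
        (e_cut + e_lumo) / 2
      } else {
        e_cut
      }
    } else {
      ef <- min(energies) - 1
    }
    return(structure(list(fermi_energy = ef, occupations = f,
                          energies = energies, n_electrons = n_electrons,
                          t_el = t_el),
                     class = "occupation_result"))
  }
  kt <- .k_boltzmann * t_el
  count <- function(ef) sum(1 / (1 + exp((energies - ef) / kt)))
  if (n_electrons == 0) {
    ef <- min(energies) - 60 * kt
  } else if (n_electrons == n_lev) {
    ef <- max(energies) + 60 * kt
  } else {
    lo <- min(energies) - 60 * kt
    hi <- max(energies) + 60 * kt
    for (it in 1:200) {
      ef <- (lo + hi) / 2
      c_mid <- count(ef)
      if (abs(c_mid - n_electrons) < 1e-12) break
      if (c_mid < n_electrons) lo <- ef else hi <- ef
    }
  }
  f <- 1 / (1 + exp((energies - ef) / kt))
  structure(list(fermi_energy = ef, occupations = f, energies = energies,
                 n_electrons = n_electrons, t_el = t_el),
            class = "occupation_result")
}

#' @export
print.occupation_result <- function(x, ...) {
  cat(sprintf("<occupation_result> %d levels, %g electrons, T_el = %g K, E_F = %.6f\n",
              length(x$occupations), x$n_electrons, x$t_el, x$fermi_energy))
  invisible(x)
}

#' N_FOD: occupation-space fractional orbital density measure
#'
#' Sums `1 - f_i` over levels below the Fermi energy and `f_i` over levels
#' at or above it. Zero for a gapped closed-shell filling at low
#' temperature; approaches 2 for two electrons shared by a degenerate
#' frontier manifold (separated-radical limit). Levels within `tol` of the
#' Fermi energy count as "not below", which makes the degenerate biradical
#' limit yield exactly 2.
#'
#' @param occ an `occupation_result`.
#' @param energies the spin-orbital energies; defaults to those stored in
#'   `occ`.
#' @param tol tolerance for "at the Fermi energy" (energy units, 1e-9).
#' @return non-negative scalar N_FOD.
#' @export
n_fod <- function(occ, energies = occ$energies, tol = 1e-9) {
  f <- occ$occupations
  below <- energies < occ$fermi_energy - tol
  sum(1 - f[below]) + sum(f[!below])
}

#' Occupations and N_FOD for a spectrum in one call
#'
#' @inheritParams fermi_occupations
#' @return an `occupation_result` with an `n_fod` field added.
#' @export
fermi_fod <- function(energies, n_electrons, t_el) {
  occ <- fermi_occupations(energies, n_electrons, t_el)
  occ$n_fod <- n_fod(occ, energies)
  occ
}

#' Recommended electronic temperature for a density functional
#'
#' Affine convention linking the optimal Fermi-smearing electronic
#' temperature to the fraction of nonlocal Fock exchange a_x:
#' T_el/K = 5000 + 20000 * a_x. A pure GGA-type functional (a_x = 0) gets
#' 5000 K.
#'
#' @param a_x Fock-exchange fraction in `[0, 1]`.
#' @return electronic temperature in K.
#' @export
recommended_T_el <- function(a_x) {
  if (!is.numeric(a_x) || any(a_x < 0 | a_x > 1)) {
    stop("a_x must lie in [0, 1]", call. = FALSE)
  }
  5000 + 20000 * a_x
}

#' Label a geometry with energy, forces, dipole and multi-temperature N_FOD
#'
#' Evaluates the calculator once and computes N_FOD at every requested
#' electronic temperature from the returned spin-orbital spectrum. A
#' calculator failure yields a discarded label (the geometry is dropped
#' from dataset counts); a calculator without orbital energies yields a
#' label whose N_FOD map is empty, with a warning.
#'
#' @param geom a `bb_geometry`.
#' @param calc a `bb_calculator` with energy and forces.
#' @param temperatures electronic temperatures in K (default 0, 1000, 5000).
#' @return object of class `conformer_label`: list with `energy`, `forces`,
#'   `dipole`, `n_fod_by_temperature` (named numeric), `discarded`.
#' @export
label_geometry <- function(geom, calc, temperatures = c(0, 1000, 5000)) {
  res <- tryCatch(calc_evaluate(calc, geom),
                  bb_calc_failure = function(e) e)
  if (inherits(res, "bb_calc_failure")) {
    return(structure(list(discarded = TRUE, reason = conditionMessage(res)),
                     class = "conformer_label"))
  }
  fod <- stats::setNames(numeric(0), character(0))
  if (!is.null(res$orbitals)) {
    energies <- as.numeric(res$orbitals$energies)
    ne <- res$orbitals$n_electrons
    fod <- vapply(temperatures, function(tt) {
      occ <- fermi_occupations(energies, ne, tt)
      n_fod(occ, energies)
    }, 1.0)
    names(fod) <- as.character(temperatures)
  } else if (has_capability(calc, "orbital_energies")) {
    warning("calculator returned no orbital energies; N_FOD entries absent")
  } else {
    warning("calculator lacks orbital energies; N_FOD entries absent")
  }
  structure(list(energy = res$energy, forces = res$forces,
                 dipole = res$dipole, n_fod_by_temperature = fod,
                 discarded = FALSE),
            class = "conformer_label")
}
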