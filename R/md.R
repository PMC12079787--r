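# Constrained NVT molecular dynamics. Units: eV, Angstrom, fs, amu.

# 1 (eV/Angstrom)/amu in Angstrom/fs^2
.ev_amu_acc <- 9.648533212e-3
# Boltzmann constant in eV/K
.k_boltzmann <- 8.617333262e-5

.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
                   P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904)

element_masses <- function(elements) {
  m <- .element_mass[elements]
  if (any(is.na(m))) {
    stop("no mass tabulated for element: ",
         paste(unique(elements[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  unname(m)
}

maxwell_boltzmann_velocities <- function(masses, temperature, movable) {
  n <- length(masses)
  v <- matrix(0, n, 3)
  if (temperature > 0 && length(movable) > 0) {
    sd_v <- sqrt(.k_boltzmann * temperature * .ev_amu_acc / masses[movable])
    v[movable, ] <- stats::rnorm(3 * length(movable)) * sd_v
  }
  v
}

kinetic_energy <- function(masses, v) {
  0.5 * sum(masses * rowSums(v^2)) / .ev_amu_acc
}

#' NVT molecular dynamics with fixed atoms
#'
#' Propagates the free atoms while `fixed_atoms` never move. The default
#' thermostat is Langevin (BAOAB splitting) at 300 K with friction
#' 0.01 fs^-1; `thermostat = "none"` gives plain velocity Verlet (NVE after
#' the initial thermal kick), useful for energy-conservation checks.
#' Velocities are initialized from the Maxwell-Boltzmann distribution at
#' `temperature` with the given seed; fixed atoms start and stay at zero
#' velocity. Snapshots are recorded every `t_dump` fs: the defaults
#' (1 ps, dump every 10 fs) give 100 snapshots.
#'
#' On a calculator failure the segment is cut: snapshots already taken are
#' kept, the result is flagged `completed = FALSE`.
#'
#' @param geom starting `bb_geometry`.
#' @param fixed_atoms integer indices held fixed (may be empty).
#' @param calc a `bb_calculator` providing forces.
#' @param t_md run length (ps, default 1).
#' @param dt timestep (fs, default 0.5).
#' @param t_dump snapshot interval (fs, default 10).
#' @param temperature target temperature (K, default 300).
#' @param thermostat `"langevin"` or `"none"`.
#' @param friction Langevin friction (fs^-1, default 0.01).
#' @param seed integer seed for velocity initialization and thermostat noise.
#' @param distance_bond optional `c(a, b)`: constrain this pair's distance
#'   (RATTLE) instead of fixing positions; used with `fixed_atoms = integer(0)`.
#' @param keep_energies also record per-snapshot potential/kinetic energy.
#' @return list with `snapshots` (list of `bb_geometry`, provenance origin
#'   `"md"`), `completed`, `failed_at` (NA or failing step), and optionally
#'   `energies` (data.frame step/pe/ke).
#' @export
constrained_md <- function(geom, fixed_atoms, calc, t_md = 1, dt = 0.5,
                           t_dump = 10, temperature = 300,
                           thermostat = c("langevin", "none"),
                           friction = 0.01, seed = 0L,
                           distance_bond = NULL, keep_energies = FALSE) {
  thermostat <- match.arg(thermostat)
  n_steps <- as.integer(round(t_md * 1000 / dt))
  dump_every <- as.integer(round(t_dump / dt))
  if (abs(t_dump / dt - dump_every) > 1e-9 || dump_every < 1) {
    stop("dt must divide t_dump", call. = FALSE)
  }
  n <- n_atoms(geom)
  movable <- setdiff(seq_len(n), fixed_atoms)
  masses <- element_masses(geom$elements)
  target <- if (!is.null(distance_bond)) {
    atom_distance(geom, distance_bond[1], distance_bond[2])
  } else NA_real_

  x <- geom$coords
  v <- with_seed(seed, maxwell_boltzmann_velocities(masses, temperature, movable))
  if (!is.null(distance_bond)) v <- project_pair(v, x, distance_bond[1], distance_bond[2])

  c1 <- exp(-friction * dt)
  c2 <- sqrt((1 - c1^2) * .k_boltzmann * temperature * .ev_amu_acc / masses)

  snapshots <- list()
  energies <- if (keep_energies) {
    data.frame(step = integer(0), pe = numeric(0), ke = numeric(0))
  } else NULL
  cur_step <- 0L

  eval_forces <- function(x) {
    g <- geom; g$coords <- x
    calc_evaluate(calc, g)
  }

  initial <- NULL
  res <- tryCatch({
    ev <- eval_forces(x)
    if (keep_energies) {
      initial <- list(pe = ev$energy, ke = kinetic_energy(masses, v))
    }
    acc <- ev$forces / masses * .ev_amu_acc
    acc[fixed_atoms, ] <- 0
    noise_stream <- with_seed(seed + 1L, stats::rnorm(3 * n * n_steps))
    dim(noise_stream) <- c(n, 3, n_steps)
    for (step in seq_len(n_steps)) {
      cur_step <- step
      v[movable, ] <- v[movable, ] + 0.5 * dt * acc[movable, , drop = FALSE]
      if (!is.null(distance_bond)) v <- project_pair(v, x, distance_bond[1], distance_bond[2])
      x[movable, ] <- x[movable, ] + 0.5 * dt * v[movable, , drop = FALSE]
      if (thermostat == "langevin") {
        v[movable, ] <- c1 * v[movable, , drop = FALSE] +
          c2[movable] * noise_stream[movable, , step]
        if (!is.null(distance_bond)) v <- project_pair(v, x, distance_bond[1], distance_bond[2])
      }
      x[movable, ] <- x[movable, ] + 0.5 * dt * v[movable, , drop = FALSE]
      if (!is.null(distance_bond)) {
        x <- shake_pair(x, distance_bond[1], distance_bond[2], target)
      }
      ev <- eval_forces(x)
      acc <- ev$forces / masses * .ev_amu_acc
      acc[fixed_atoms, ] <- 0
      v[movable, ] <- v[movable, ] + 0.5 * dt * acc[movable, , drop = FALSE]
      if (!is.null(distance_bond)) v <- project_pair(v, x, distance_bond[1], distance_bond[2])
      if (step %% dump_every == 0L) {
        snap <- geom
        snap$coords <- x
        snap <- with_provenance(snap, origin = "md",
                                snapshot = step %/% dump_every)
        snapshots[[length(snapshots) + 1L]] <- snap
        if (keep_energies) {
          energies <- rbind(energies,
                            data.frame(step = step, pe = ev$energy,
                                       ke = kinetic_energy(masses, v)))
        }
      }
    }
    list(snapshots = snapshots, completed = TRUE, failed_at = NA_integer_,
         energies = energies, initial = initial)
  }, bb_calc_failure = function(e) {
    list(snapshots = snapshots, completed = FALSE,
         failed_at = cur_step, energies = energies, initial = initial)
  })
  res
}
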