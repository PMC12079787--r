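# The staged bond-elongation sampling loop: elongate -> constrained
# optimization (save) -> constrained NVT MD -> minimax-selected snapshots
# (save), repeated over the elongation schedule for every unique bond.

#' Sampler configuration
#'
#' Defaults follow the workflow's standard conditions: a two-stage schedule
#' to 2x the equilibrium length in 10 steps then 3x in 5 more, 1 ps of NVT
#' MD per step at a 0.5 fs timestep with snapshots every 10 fs, and up to
#' 10 diverse snapshots kept per MD segment — 15 optimization conformers
#' plus 150 MD conformers per bond when nothing fails. The MD temperature
#' and thermostat are workflow choices, not prescribed by the sampling
#' scheme: Langevin at 300 K with friction 0.01 fs^-1.
#'
#' @param stages elongation stages, list of `c(multiplier, step_count)`.
#' @param t_md MD duration per step (ps); 0 disables MD.
#' @param dt MD timestep (fs); must divide `t_dump`.
#' @param t_dump snapshot interval (fs); must divide `t_md * 1000`.
#' @param snapshot_cap max diverse snapshots kept per MD segment (>= 1).
#' @param md_temperature thermostat temperature (K).
#' @param thermostat `"langevin"` or `"none"`.
#' @param friction Langevin friction (fs^-1).
#' @param opt_fmax optimization force threshold (eV/Angstrom).
#' @param opt_max_iter optimization iteration cap.
#' @param rng_seed base seed; per-step MD seeds are derived from it.
#' @param continue_from start each elongation from the previous step's
#'   `"opt"` geometry (deterministic default) or its last `"md"` frame.
#' @param constraint `"fixed"` holds both bond atoms at fixed Cartesian
#'   positions (the workflow default); `"distance"` constrains only their
#'   mutual distance.
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(stages = list(c(2, 10), c(3, 5)), t_md = 1,
                           dt = 0.5, t_dump = 10, snapshot_cap = 10L,
                           md_temperature = 300, thermostat = "langevin",
                           friction = 0.01, opt_fmax = 0.05,
                           opt_max_iter = 500L, rng_seed = 0L,
                           continue_from = c("opt", "md"),
                           constraint = c("fixed", "distance")) {
  continue_from <- match.arg(continue_from)
  constraint <- match.arg(constraint)
  if (abs(t_dump / dt - round(t_dump / dt)) > 1e-9) {
    stop("dt must divide t_dump", call. = FALSE)
  }
  if (t_md > 0 && abs(t_md * 1000 / t_dump - round(t_md * 1000 / t_dump)) > 1e-9) {
    stop("t_dump must divide t_md * 1000", call. = FALSE)
  }
  if (snapshot_cap < 1) stop("snapshot_cap must be >= 1", call. = FALSE)
  mult <- vapply(stages, function(s) s[[1]], 1.0)
  if (any(diff(c(1, mult)) <= 0)) {
    stop("stage multipliers must be strictly increasing", call. = FALSE)
  }
  structure(list(stages = stages, t_md = t_md, dt = dt, t_dump = t_dump,
                 snapshot_cap = as.integer(snapshot_cap),
                 md_temperature = md_temperature, thermostat = thermostat,
                 friction = friction, opt_fmax = opt_fmax,
                 opt_max_iter = as.integer(opt_max_iter),
                 rng_seed = as.integer(rng_seed),
                 continue_from = continue_from, constraint = constraint),
            class = "sampler_config")
}

#' Run the staged elongation workflow on one bond
#'
#' For each target of the elongation schedule: displace the bond atoms to
#' the target distance, relax the rest of the molecule with the bond atoms
#' constrained, save the optimized geometry, run constrained NVT MD, and
#' save up to `snapshot_cap` minimax-selected snapshots. Every saved
#' geometry carries full provenance (molecule, bond, step, origin,
#' snapshot index). Calculator failures discard the affected geometry or
#' cut the affected MD segment; counts are reported.
#'
#' @param record a `molecule_record`.
#' @param start embedded equilibrium `bb_geometry`.
#' @param bond integer `c(a, b)`, a bond of the record.
#' @param calc a `bb_calculator` providing forces.
#' @param config a [sampler_config()].
#' @return object of class `trajectory_result`: `opt_geometries`,
#'   `md_geometries`, `steps` (per-step metadata data.frame),
#'   `discarded_count`, `bond`, `l0`, `schedule`.
#' @export
run_bond_trajectory <- function(record, start, bond, calc, config = sampler_config()) {
  a <- min(bond); b <- max(bond)
  if (!any(record$bonds$a == a & record$bonds$b == b)) {
    stop(sprintf("atoms %d-%d are not bonded in '%s'", a, b,
                 record$identifier), call. = FALSE)
  }
  bond <- as.integer(c(a, b))
  l0 <- atom_distance(start, a, b)
  sched <- build_schedule(l0, config$stages)
  geom <- with_provenance(start, molecule_id = record$identifier, bond = bond)

  opt_geoms <- list()
  md_geoms <- list()
  discarded <- 0L
  steps <- data.frame(step = integer(0), target = numeric(0),
                      stage = integer(0), converged = logical(0),
                      opt_discarded = logical(0), md_completed = logical(0),
                      n_md_saved = integer(0))

  for (t in seq_along(sched$targets)) {
    target <- sched$targets[t]
    g_e <- elongate(geom, bond, target)
    if (config$constraint == "fixed") {
      opt <- constrained_optimize(g_e, bond, calc, fmax = config$opt_fmax,
                                  max_iter = config$opt_max_iter)
    } else {
      opt <- distance_constrained_optimize(g_e, bond, calc,
                                           fmax = config$opt_fmax,
                                           max_iter = config$opt_max_iter)
    }
    n_md_saved <- 0L
    md_completed <- NA
    if (!opt$discarded) {
      g_opt <- with_provenance(opt$geometry, step = t, origin = "opt",
                               snapshot = 0L)
      opt_geoms[[length(opt_geoms) + 1L]] <- g_opt
      if (config$t_md > 0) {
        md <- constrained_md(
          g_opt,
          fixed_atoms = if (config$constraint == "fixed") bond else integer(0),
          calc = calc, t_md = config$t_md, dt = config$dt,
          t_dump = config$t_dump, temperature = config$md_temperature,
          thermostat = config$thermostat, friction = config$friction,
          seed = config$rng_seed + 1000L * t,
          distance_bond = if (config$constraint == "distance") bond else NULL)
        md_completed <- md$completed
        if (!md$completed) discarded <- discarded + 1L
        if (length(md$snapshots) > 0) {
          desc <- lapply(md$snapshots, describe_snapshot)
          sel <- minimax_select(desc, config$snapshot_cap)
          for (s in sel) {
            snap <- with_provenance(md$snapshots[[s]], step = t)
            md_geoms[[length(md_geoms) + 1L]] <- snap
          }
          n_md_saved <- length(sel)
        }
        if (config$continue_from == "md" && length(md$snapshots) > 0) {
          geom <- md$snapshots[[length(md$snapshots)]]
        } else {
          geom <- g_opt
        }
      } else {
        geom <- g_opt
      }
    } else {
      discarded <- discarded + 1L
      geom <- g_e  # carry the elongated geometry forward
    }
    steps <- rbind(steps, data.frame(
      step = t, target = target, stage = sched$stage[t],
      converged = opt$converged, opt_discarded = opt$discarded,
      md_completed = md_completed, n_md_saved = n_md_saved))
  }

  structure(list(opt_geometries = opt_geoms, md_geometries = md_geoms,
                 steps = steps, discarded_count = discarded,
                 bond = bond, l0 = l0, schedule = sched,
                 molecule_id = record$identifier),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("<trajectory_result> %s bond %d-%d: %d opt + %d md conformers (%d discarded)\n",
              x$molecule_id, x$bond[1], x$bond[2], length(x$opt_geometries),
              length(x$md_geometries), x$discarded_count))
  invisible(x)
}

#' Run the sampling workflow over every unique bond of a molecule
#'
#' Deduplicates the molecule's bonds by bond hash and runs
#' [run_bond_trajectory()] once per equivalence-class representative, all
#' starting from the same embedded equilibrium geometry.
#'
#' @param record a `molecule_record` (should pass [passes_filter()]).
#' @param calc a `bb_calculator`.
#' @param config a [sampler_config()].
#' @param start optional embedded `bb_geometry`; embedded with
#'   `embed_seed` when missing.
#' @param embed_seed seed for [embed_geometry()] when `start` is missing.
#' @return list of `trajectory_result`, one per unique bond, with a
#'   `summary` attribute (per-bond conformer and discard counts).
#' @export
run_molecule <- function(record, calc, config = sampler_config(),
                         start = NULL, embed_seed = 0L) {
  if (is.null(start)) start <- embed_geometry(record, seed = embed_seed)
  ub <- unique_bonds(record, scope = "per_molecule")
  out <- vector("list", nrow(ub))
  for (i in seq_len(nrow(ub))) {
    out[[i]] <- run_bond_trajectory(record, start, c(ub$a[i], ub$b[i]),
                                    calc, config)
  }
  attr(out, "summary") <- data.frame(
    a = ub$a, b = ub$b, class_size = ub$class_size,
    n_opt = vapply(out, function(t) length(t$opt_geometries), 1L),
    n_md = vapply(out, function(t) length(t$md_geometries), 1L),
    discarded = vapply(out, function(t) t$discarded_count, 1L))
  out
}
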