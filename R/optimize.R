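# Constrained local geometry optimization. The workflow default holds the
# two selected bond atoms at fixed Cartesian positions and relaxes the rest
# (L-BFGS-B over the free coordinates); a distance-only constraint mode
# (FIRE descent with SHAKE-style projection) is available behind a flag.

#' Geometry optimization with fixed atoms
#'
#' Relaxes all atoms except `fixed_atoms`, whose coordinates are returned
#' bit-identical to the input. Convergence means the maximum force
#' magnitude on any free atom is at most `fmax`. Calculator failures are
#' not fatal: the geometry comes back flagged `discarded`, mirroring how
#' non-converged quantum-chemistry labels are dropped.
#'
#' @param geom a `bb_geometry`.
#' @param fixed_atoms integer indices of atoms to hold fixed (nonempty).
#' @param calc a `bb_calculator` providing forces.
#' @param fmax convergence threshold on the per-atom force norm
#'   (calculator force units, default 0.05).
#' @param max_iter maximum optimizer iterations (default 500).
#' @return list with `geometry`, `converged` (logical), `discarded`
#'   (logical), and `max_force` on the free atoms.
#' @export
constrained_optimize <- function(geom, fixed_atoms, calc, fmax = 0.05,
                                 max_iter = 500L) {
  if (length(fixed_atoms) == 0) stop("fixed_atoms must be nonempty", call. = FALSE)
  free <- setdiff(seq_len(n_atoms(geom)), fixed_atoms)
  if (length(free) == 0) {
    return(list(geometry = geom, converged = TRUE, discarded = FALSE,
                max_force = 0))
  }
  x0 <- geom$coords
  set_free <- function(par) {
    x <- x0
    x[free, ] <- matrix(par, ncol = 3)
    x
  }
  fn <- function(par) {
    g <- geom; g$coords <- set_free(par)
    calc_evaluate(calc, g)$energy
  }
  gr <- function(par) {
    g <- geom; g$coords <- set_free(par)
    -as.vector(calc_evaluate(calc, g)$forces[free, , drop = FALSE])
  }
  par <- as.vector(x0[free, , drop = FALSE])
  res <- tryCatch({
    for (round in 1:3) {
      opt <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                          control = list(maxit = max_iter, factr = 10))
      par <- opt$par
      g <- geom; g$coords <- set_free(par)
      f <- calc_evaluate(calc, g)$forces
      mf <- max(sqrt(rowSums(f[free, , drop = FALSE]^2)))
      if (mf <= fmax) break
    }
    list(geometry = g, converged = mf <= fmax, discarded = FALSE,
         max_force = mf)
  }, bb_calc_failure = function(e) {
    list(geometry = geom, converged = FALSE, discarded = TRUE,
         max_force = NA_real_)
  })
  res
}

# Remove the component of per-atom vectors (forces/velocities) that would
# change the a-b distance: subtract the antisymmetric along-bond part.
project_pair <- function(vec, x, a, b) {
  u <- x[b, ] - x[a, ]
  u <- u / sqrt(sum(u^2))
  lam <- sum((vec[b, ] - vec[a, ]) * u) / 2
  vec[a, ] <- vec[a, ] + lam * u
  vec[b, ] <- vec[b, ] - lam * u
  vec
}

shake_pair <- function(x, a, b, target) {
  dv <- x[b, ] - x[a, ]
  d <- sqrt(sum(dv^2))
  u <- dv / d
  corr <- (target - d) / 2
  x[a, ] <- x[a, ] - corr * u
  x[b, ] <- x[b, ] + corr * u
  x
}

#' Geometry optimization with a single distance constraint
#'
#' FIRE descent in which only the `bond` pair's mutual distance is
#' constrained (to its current value); the pair may translate and rotate.
#' Convergence is on the maximum constrained-projected force.
#'
#' @inheritParams constrained_optimize
#' @param bond integer vector `c(a, b)` whose distance is held.
#' @param dt_start,dt_max FIRE timestep bounds (fs).
#' @return as [constrained_optimize()].
#' @export
distance_constrained_optimize <- function(geom, bond, calc, fmax = 0.05,
                                          max_iter = 500L, dt_start = 0.5,
                                          dt_max = 2.0) {
  a <- bond[1]; b <- bond[2]
  target <- atom_distance(geom, a, b)
  x <- geom$coords
  n <- nrow(x)
  v <- matrix(0, n, 3)
  dt <- dt_start
  alpha <- 0.1
  n_pos <- 0L
  res <- tryCatch({
    mf <- Inf
    for (it in seq_len(max_iter)) {
      g <- geom; g$coords <- x
      f <- project_pair(calc_evaluate(calc, g)$forces, x, a, b)
      mf <- max(sqrt(rowSums(f^2)))
      if (mf <= fmax) break
      p <- sum(v * f)
      if (p > 0) {
        n_pos <- n_pos + 1L
        fn <- sqrt(sum(f^2)); vn <- sqrt(sum(v^2))
        v <- (1 - alpha) * v + alpha * vn * f / max(fn, 1e-12)
        if (n_pos > 5L) {
          dt <- min(dt * 1.1, dt_max)
          alpha <- alpha * 0.99
        }
      } else {
        v[] <- 0
        dt <- dt * 0.5
        alpha <- 0.1
        n_pos <- 0L
      }
      v <- v + dt * f * .ev_amu_acc
      v <- project_pair(v, x, a, b)
      x <- shake_pair(x + dt * v, a, b, target)
    }
    g <- geom; g$coords <- x
    list(geometry = g, converged = mf <= fmax, discarded = FALSE,
         max_force = mf)
  }, bb_calc_failure = function(e) {
    list(geometry = geom, converged = FALSE, discarded = TRUE,
         max_force = NA_real_)
  })
  res
}
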