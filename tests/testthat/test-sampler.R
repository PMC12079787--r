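test_that("elongation schedule spaces targets per stage and hits multiples exactly", {
  s <- build_schedule(1.0)
  expect_equal(s$targets,
               c(seq(1.1, 2.0, by = 0.1), seq(2.2, 3.0, by = 0.2)),
               tolerance = 1e-12)
  expect_identical(s$targets[10], 2.0)
  expect_identical(s$targets[15], 3.0)

  s2 <- build_schedule(1.54)
  expect_identical(s2$targets[15] / 1.54, 3.0)
  expect_identical(s2$targets[10] / 1.54, 2.0)

  expect_equal(build_schedule(1.0, list(c(2, 1)))$targets, 2.0)
  expect_error(build_schedule(1.0, list(c(2, 5), c(1.5, 5))), "increasing")
  expect_error(build_schedule(-1), "positive")
})

test_that("elongation displaces only the bond pair, symmetrically", {
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1)))
  g2 <- elongate(g, c(1, 2), 1.5)
  expect_equal(g2$coords, rbind(c(0, 0, -0.25), c(0, 0, 1.25)))

  ge <- ethane_geom()
  target <- atom_distance(ge, 1, 2)
  expect_identical(elongate(ge, c(1, 2), target)$coords, ge$coords)

  g3 <- elongate(ge, c(1, 2), 2.5)
  expect_identical(g3$coords[3:8, ], ge$coords[3:8, ])
  # midpoint preserved
  expect_equal((g3$coords[1, ] + g3$coords[2, ]) / 2,
               (ge$coords[1, ] + ge$coords[2, ]) / 2, tolerance = 1e-12)

  g0 <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(elongate(g0, c(1, 2), 1), "coincident")
})

test_that("fixed-atom optimization reaches the analytic harmonic minimum", {
  # triatomic: two fixed anchors 1.6 apart, free atom bonded to both with
  # r0 = 1 -> zero-energy minimum with both bond lengths exactly 1
  bonds <- rbind(c(1, 3), c(2, 3))
  calc <- harmonic_calculator(bonds, k = 10, r0 = 1)
  g <- geometry(c("H", "H", "H"),
                rbind(c(0, 0, 0), c(1.6, 0, 0), c(1.3, 0.8, 0.4)))
  res <- constrained_optimize(g, c(1, 2), calc, fmax = 1e-6)
  expect_true(res$converged)
  expect_identical(res$geometry$coords[1:2, ], g$coords[1:2, ])
  expect_equal(atom_distance(res$geometry, 1, 3), 1, tolerance = 1e-5)
  expect_equal(atom_distance(res$geometry, 2, 3), 1, tolerance = 1e-5)
  expect_lt(calc_evaluate(calc, res$geometry)$energy, 1e-9)

  # already-optimal input returns unchanged within tolerance
  g_opt <- res$geometry
  res2 <- constrained_optimize(g_opt, c(1, 2), calc, fmax = 1e-6)
  expect_true(res2$converged)
  expect_equal(res2$geometry$coords, g_opt$coords, tolerance = 1e-8)
})

test_that("distance-constrained optimization preserves the pair distance only", {
  bonds <- rbind(c(1, 2), c(2, 3))
  calc <- harmonic_calculator(bonds, k = 10, r0 = 1)
  g <- geometry(c("H", "H", "H"),
                rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.1, 0.9, 0)))
  d0 <- atom_distance(g, 1, 2)
  res <- distance_constrained_optimize(g, c(1, 2), calc, fmax = 1e-4)
  expect_true(res$converged)
  expect_equal(atom_distance(res$geometry, 1, 2), d0, tolerance = 1e-9)
  # the 2-3 bond relaxes to its equilibrium length
  expect_equal(atom_distance(res$geometry, 2, 3), 1, tolerance = 1e-3)
})

test_that("constrained MD dumps the expected snapshots and never moves fixed atoms", {
  md <- constrained_md(ethane_geom(), c(1, 2), ethane_calc(), seed = 11)
  expect_length(md$snapshots, 100)
  expect_true(md$completed)
  for (s in md$snapshots[c(1, 50, 100)]) {
    expect_identical(s$coords[1:2, ], ethane_geom()$coords[1:2, ])
  }
  expect_equal(md$snapshots[[7]]$provenance$snapshot, 7L)
  expect_equal(md$snapshots[[7]]$provenance$origin, "md")
})

test_that("velocity-Verlet total energy is conserved without a thermostat", {
  md <- constrained_md(ethane_geom(), c(1, 2), ethane_calc(),
                       thermostat = "none", temperature = 300, seed = 3,
                       keep_energies = TRUE)
  tot <- md$energies$pe + md$energies$ke
  e0 <- md$initial$pe + md$initial$ke
  expect_lt(max(abs(tot - e0)), 0.01 * md$initial$ke)
})

test_that("a full default bond run yields 15 + 150 provenance-tagged conformers", {
  traj <- ethane_cc_run()
  expect_length(traj$opt_geometries, 15)
  expect_length(traj$md_geometries, 150)
  expect_equal(traj$discarded_count, 0)
  expect_true(all(traj$steps$converged))

  # constraint exactness on every saved conformer
  opt_fixed <- lapply(traj$opt_geometries, function(g) g$coords[1:2, ])
  for (g in c(traj$opt_geometries, traj$md_geometries)) {
    p <- g$provenance
    expect_equal(atom_distance(g, 1, 2), traj$schedule$targets[p$step],
                 tolerance = 1e-6)
    expect_identical(g$coords[1:2, ], opt_fixed[[p$step]])
    expect_false(is.na(p$origin))
    expect_equal(p$molecule_id, "ethane")
  }
  expect_equal(vapply(traj$opt_geometries, function(g) g$provenance$step, 1L),
               1:15)
})

test_that("disabling MD leaves only the optimization conformers", {
  cfg <- sampler_config(t_md = 0, rng_seed = 1)
  traj <- run_bond_trajectory(ethane_record(), ethane_geom(), c(1, 2),
                              ethane_calc(), cfg)
  expect_length(traj$opt_geometries, 15)
  expect_length(traj$md_geometries, 0)
})

test_that("the sampling loop is reproducible under a fixed seed", {
  cfg <- sampler_config(stages = list(c(2, 2)), t_md = 0.05, rng_seed = 9)
  t1 <- run_bond_trajectory(ethane_record(), ethane_geom(), c(1, 2),
                            ethane_calc(), cfg)
  t2 <- run_bond_trajectory(ethane_record(), ethane_geom(), c(1, 2),
                            ethane_calc(), cfg)
  expect_length(t1$md_geometries, 10)
  expect_identical(lapply(t1$md_geometries, `[[`, "coords"),
                   lapply(t2$md_geometries, `[[`, "coords"))
  expect_identical(lapply(t1$opt_geometries, `[[`, "coords"),
                   lapply(t2$opt_geometries, `[[`, "coords"))
})

test_that("calculator failures discard geometries instead of aborting", {
  rec <- ethane_record()
  ge <- ethane_geom()
  failing <- toy_forcefield(rec, ge, fail_if = function(g) {
    atom_distance(g, 1, 2) > 2.5
  })
  cfg <- sampler_config(stages = list(c(2, 3)), t_md = 0.05, rng_seed = 2)
  traj <- run_bond_trajectory(rec, ge, c(1, 2), failing, cfg)
  expect_lt(length(traj$opt_geometries), 3)
  expect_gt(traj$discarded_count, 0)
  expect_true(any(traj$steps$opt_discarded))
})

test_that("per-molecule runs cover each unique bond once from one start", {
  cfg <- sampler_config(stages = list(c(2, 1)), t_md = 0.02, rng_seed = 4)
  trajs <- run_molecule(methane_record(),
                        toy_forcefield(methane_record(),
                                       embed_geometry(methane_record(), 0)),
                        cfg, start = embed_geometry(methane_record(), 0))
  expect_length(trajs, 1)

  trajs_e <- run_molecule(ethane_record(), ethane_calc(), cfg,
                          start = ethane_geom())
  expect_length(trajs_e, 2)
  summ <- attr(trajs_e, "summary")
  expect_equal(summ$n_opt + summ$n_md,
               vapply(trajs_e, function(t) {
                 length(t$opt_geometries) + length(t$md_geometries)
               }, 1L))
})

test_that("invalid sampler configurations are rejected", {
  expect_error(sampler_config(dt = 0.7), "divide")
  expect_error(sampler_config(t_dump = 7), "divide")
  expect_error(sampler_config(snapshot_cap = 0), "snapshot_cap")
  expect_error(sampler_config(stages = list(c(3, 5), c(2, 5))), "increasing")
})
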