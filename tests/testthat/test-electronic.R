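test_that("Fermi occupations conserve electrons and match an independent root finder", {
  kb <- 8.617333262e-5
  # symmetry forces equal sharing
  occ <- fermi_occupations(c(0, 0), 1, 1000)
  expect_equal(occ$occupations, c(0.5, 0.5), tolerance = 1e-12)

  # gapped zero-temperature step function
  occ0 <- fermi_occupations(c(-10, -9, 9, 10), 2, 0)
  expect_equal(occ0$occupations, c(1, 1, 0, 0))
  expect_equal(occ0$fermi_energy, 0)

  set.seed(5)
  for (trial in 1:10) {
    e <- sort(rnorm(20, sd = 5))
    occ <- fermi_occupations(e, 8, 5000)
    expect_lt(abs(sum(occ$occupations) - 8), 1e-8)
    # independent scalar root finder for E_F
    kt <- kb * 5000
    ef_oracle <- uniroot(function(ef) sum(1 / (1 + exp((e - ef) / kt))) - 8,
                         c(min(e) - 10, max(e) + 10), tol = 1e-14)$root
    expect_equal(occ$fermi_energy, ef_oracle, tolerance = 1e-7)
    expect_true(all(occ$occupations >= 0 & occ$occupations <= 1))
    # monotone non-increasing in energy; f(E_F) = 1/2
    expect_true(all(diff(occ$occupations[order(e)]) <= 1e-12))
  }

  expect_error(fermi_occupations(c(0, 1), 3, 1000), "infeasible")
  expect_error(fermi_occupations(c(0, 1), 1, -5), "t_el")
})

test_that("degenerate levels at a zero-temperature Fermi cut share electrons equally", {
  occ <- fermi_occupations(c(-5, 0, 0, 0, 5), 2, 0)
  expect_equal(occ$occupations, c(1, 1 / 3, 1 / 3, 1 / 3, 0))
  expect_equal(sum(occ$occupations), 2)
})

test_that("N_FOD matches the literal delta-bookkeeping formula on random spectra", {
  nfod_literal <- function(energies, f, ef) {
    # delta_1, delta_2 = (1, 1) below E_F, (0, -1) otherwise:
    # contribution delta_1 + delta_2 * f below, f above
    tot <- 0
    for (i in seq_along(energies)) {
      if (energies[i] < ef - 1e-9) {
        tot <- tot + 1 - f[i]
      } else {
        tot <- tot + f[i]
      }
    }
    tot
  }
  set.seed(17)
  for (trial in 1:1000) {
    n <- sample(4:24, 1)
    e <- rnorm(n, sd = 4)
    ne <- sample(seq_len(n - 1), 1)
    t_el <- sample(c(500, 1000, 5000, 20000), 1)
    occ <- fermi_occupations(e, ne, t_el)
    expect_lt(abs(n_fod(occ) -
                    nfod_literal(e, occ$occupations, occ$fermi_energy)),
              1e-10)
  }
})

test_that("N_FOD limits: gapped closed shell at low T gives 0, biradical gives 2", {
  # gapped closed shell, T -> 0
  occ0 <- fermi_occupations(c(-8, -8, 8, 8), 2, 0)
  expect_equal(n_fod(occ0), 0)
  occ_small <- fermi_occupations(c(-8, -8, 8, 8), 2, 50)
  expect_lt(n_fod(occ_small), 1e-10)

  # two electrons in a doubly degenerate (four spin-level) frontier
  # manifold: separated-radical limit, N_FOD = 2 at any positive T
  for (t_el in c(300, 1000, 5000)) {
    occ <- fermi_occupations(c(0, 0, 0, 0), 2, t_el)
    expect_equal(n_fod(occ), 2, tolerance = 1e-9)
  }
  # with far-away core and virtual levels present
  occ <- fermi_fod(c(rep(-10, 4), rep(0, 4), rep(10, 4)), 6, 5000)
  expect_equal(occ$n_fod, 2, tolerance = 1e-6)

  # smearing only broadens: N_FOD at 0 K never exceeds N_FOD at 5000 K
  set.seed(23)
  for (trial in 1:10) {
    e <- sort(rnorm(12, sd = 3))
    ne <- 6
    expect_lte(n_fod(fermi_occupations(e, ne, 0)),
               n_fod(fermi_occupations(e, ne, 5000)) + 1e-9)
  }
})

test_that("high-temperature limit spreads electrons evenly over all levels", {
  e <- c(-3, -1, 0, 2, 5)
  occ <- fermi_occupations(e, 2, 1e9)
  expect_equal(occ$occupations, rep(2 / 5, 5), tolerance = 1e-3)
})

test_that("recommended electronic temperature is affine in the exchange fraction", {
  expect_equal(recommended_T_el(0), 5000)
  expect_equal(recommended_T_el(1), 25000)
  a <- c(0.1, 0.25, 0.6)
  expect_equal(recommended_T_el(a) - recommended_T_el(0), 20000 * a)
  expect_error(recommended_T_el(1.2), "\\[0, 1\\]")
  expect_error(recommended_T_el(-0.1), "\\[0, 1\\]")
})

test_that("geometry labels carry N_FOD that grows as the sampled bond stretches", {
  traj <- ethane_cc_run()
  calc <- ethane_calc()
  labels <- lapply(traj$opt_geometries, label_geometry, calc = calc)
  fod5000 <- vapply(labels, function(l) l$n_fod_by_temperature[["5000"]], 1.0)
  expect_true(all(diff(fod5000) > -1e-9))
  expect_lt(fod5000[1], 0.1)
  expect_gt(fod5000[15], 1.5)
  # smearing ordering within each label
  fod0 <- vapply(labels, function(l) l$n_fod_by_temperature[["0"]], 1.0)
  expect_true(all(fod0 <= fod5000 + 1e-9))
  expect_named(labels[[1]]$n_fod_by_temperature, c("0", "1000", "5000"))
})

test_that("failed label evaluations are flagged and excluded from datasets", {
  rec <- ethane_record()
  ge <- ethane_geom()
  failing <- toy_forcefield(rec, ge, fail_if = function(g) TRUE)
  lab <- label_geometry(ge, failing)
  expect_true(lab$discarded)

  traj <- ethane_cc_run()
  fail_far <- toy_forcefield(rec, ge, fail_if = function(g) {
    atom_distance(g, g$provenance$bond[1], g$provenance$bond[2]) > 3
  })
  recs <- collect_records(traj, fail_far)
  expect_lt(length(recs), 165)
  expect_true(all(vapply(recs, function(r) !r$label$discarded, TRUE)))
})

test_that("calculators without orbital energies yield labels without N_FOD", {
  calc <- harmonic_calculator(rbind(c(1, 2)), k = 5, r0 = 1)
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.2)))
  expect_warning(lab <- label_geometry(g, calc), "orbital")
  expect_length(lab$n_fod_by_temperature, 0)
  expect_false(lab$discarded)
})
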