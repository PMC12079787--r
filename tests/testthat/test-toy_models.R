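test_that("toy force field is zero at its calibrated equilibrium (no 1-4 pairs)", {
  rec <- methane_record()
  g <- embed_geometry(rec, seed = 0)
  calc <- toy_forcefield(rec, g)  # methane has no pairs >2 bonds apart
  ev <- calc_evaluate(calc, g)
  expect_equal(ev$energy, 0, tolerance = 1e-12)
  expect_lt(max(abs(ev$forces)), 1e-10)
})

test_that("a stretched bond contributes exactly its closed-form harmonic energy", {
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.0)))
  rec <- structure(list(
    identifier = "h2", smiles = "[H][H]", elements = c("H", "H"),
    bonds = data.frame(a = 1L, b = 2L, order = 1, aromatic = FALSE),
    explicit_h_counts = c(0L, 0L), valences = c(1L, 1L),
    formal_charges = c(0L, 0L), aromatic = c(FALSE, FALSE),
    radical_electrons = c(0L, 0L)), class = "molecule_record")
  k <- 25
  calc <- toy_forcefield(rec, g, k_bond = k)
  g2 <- elongate(g, c(1, 2), 1.4)
  expect_equal(calc_evaluate(calc, g2)$energy, 0.5 * k * 0.4^2,
               tolerance = 1e-12)
})

test_that("analytic forces match central finite differences on random geometries", {
  suite <- make_fixture_suite(seed = 1, n_random = 2)
  set.seed(99)
  h <- 1e-5
  for (nm in c("ethane", "aminoethanol", "random01")) {
    rec <- suite$records[[nm]]
    g0 <- suite$geometries[[nm]]
    calc <- toy_forcefield(rec, g0)
    for (rep in 1:3) {
      g <- g0
      g$coords <- g$coords + matrix(rnorm(length(g$coords), sd = 0.05),
                                    ncol = 3)
      f <- calc_evaluate(calc, g)$forces
      n <- nrow(g$coords)
      num <- matrix(0, n, 3)
      for (i in seq_len(n)) for (kk in 1:3) {
        gp <- g; gp$coords[i, kk] <- gp$coords[i, kk] + h
        gm <- g; gm$coords[i, kk] <- gm$coords[i, kk] - h
        num[i, kk] <- -(calc_evaluate(calc, gp)$energy -
                          calc_evaluate(calc, gm)$energy) / (2 * h)
      }
      expect_lt(max(abs(num - f)), 1e-4)
    }
  }
})

test_that("mock spectrum closes its gap as the reference bond stretches", {
  sp0 <- toy_spectrum(7, r = 1.5, r0 = 1.5)
  expect_equal(sp0$n_electrons, 14)
  expect_length(sp0$energies, 28)
  gap <- function(r) {
    e <- toy_spectrum(7, r, 1.5)$energies
    sort(e)[15] - sort(e)[14]
  }
  gaps <- vapply(c(1.5, 2.0, 2.5, 3.5, 4.5), gap, 1.0)
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[5], 0.1)
  # compressed bond keeps the equilibrium gap (clamped)
  expect_equal(gap(1.2), gap(1.5))

  # fixed-T N_FOD is non-decreasing in the stretch
  fods <- vapply(seq(1.5, 4.5, by = 0.5), function(r) {
    sp <- toy_spectrum(7, r, 1.5)
    fermi_fod(sp$energies, sp$n_electrons, 5000)$n_fod
  }, 1.0)
  expect_true(all(diff(fods) > -1e-12))
})

test_that("toy dipole comes from neutrality-shifted fixed charges", {
  rec <- methane_record()
  g <- embed_geometry(rec, seed = 0)
  calc <- toy_forcefield(rec, g)
  d1 <- calc_evaluate(calc, g)$dipole
  expect_length(d1, 3)
  # translation invariance (charges sum to zero)
  g2 <- g; g2$coords <- g$coords + 5
  expect_equal(calc_evaluate(calc, g2)$dipole, d1, tolerance = 1e-10)
})

test_that("fixture suite is deterministic and filter-compliant", {
  s1 <- make_fixture_suite(seed = 0, n_random = 4)
  s2 <- make_fixture_suite(seed = 0, n_random = 4)
  expect_identical(s1$table, s2$table)
  expect_identical(lapply(s1$geometries, `[[`, "coords"),
                   lapply(s2$geometries, `[[`, "coords"))
  expect_true("dimethylbutane" %in% names(s1$records))
  expect_equal(s1$records$dimethylbutane$smiles, "CCC(C)(C)C")
  expect_true(all(vapply(s1$records, passes_filter, TRUE)))

  s3 <- make_fixture_suite(seed = 8, n_random = 4)
  expect_false(identical(s1$table$smiles, s3$table$smiles))
})
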