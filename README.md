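# bondbreakr

Automated bond-breaking conformer sampling for training reactive
machine-learned interatomic potentials.

Potentials trained on equilibrium conformers fail where reactions happen:
stretched bonds, nascent radicals, rearranging fragments. `bondbreakr`
generates exactly those geometries for small organic molecules (H/C/N/O,
≤ 7 heavy atoms by default). For every chemically distinct bond it runs a
staged elongation loop — stretch the bond, relax everything else with the
bond atoms constrained, run constrained NVT dynamics, keep a diverse
snapshot subset — and labels each saved conformer with energy, forces,
dipole, and the finite-temperature radical-character measure
N<sub>FOD</sub>.

The core pieces:

* **Bond deduplication** — bonds are grouped by an environment hash: the
  atom hash is the 5-vector (atomic number, bonded hydrogens, neighbour
  count, valence, aromatic flag); the R₃-atom hash sums atom hashes over
  the closed radius-3 neighbourhood; the bond hash is the sum over the two
  endpoints. One representative per class is sampled.
* **Staged elongation** — targets advance from l₀ to 2 l₀ in 10 equal
  steps, then to 3 l₀ in 5 more (per-step increment
  l_step = (n_e − 1) l₀ / n_steps for a single stage); both endpoints are
  exact multiples.
* **Constrained sampling** — per step: fixed-atom L-BFGS-B relaxation
  (max free-atom force ≤ 0.05 eV/Å), then 1 ps of Langevin NVT MD
  (dt = 0.5 fs, 300 K), snapshots every 10 fs, reduced to ≤ 10 by greedy
  farthest-point (minimax) selection on sorted-distance descriptors.
  Defaults yield 15 + 150 = 165 conformers per bond.
* **Occupation analysis** — Fermi–Dirac fractional occupations f_i over
  spin orbitals with the Fermi level solved by bisection, and
  N_FOD = Σ_{ε<E_F} (1 − f_i) + Σ_{ε≥E_F} f_i at electronic temperatures
  {0, 1000, 5000} K (5000 K corresponds to an exchange-free functional via
  T_el/K = 5000 + 20000·a_x).
* **Pluggable calculators** — any backend implementing the
  energy/forces/dipole/spectrum contract plugs in; a fully tested analytic
  toy force field with a gap-closing mock spectrum is bundled, so the whole
  workflow runs without any quantum-chemistry code.
* **Evaluation helpers** — reaction energy (P−R), barrier height (TS−R),
  TS−P, bond dissociation energies, and grouped MAE reports.

## Requirements and installation

R (≥ 4.1) with `igraph` and `jsonlite`, plus a `python` interpreter with
RDKit on the PATH (used for SMILES parsing and seeded, bit-reproducible 3D
embedding).

```sh
R CMD INSTALL .
```

Run the tests with:

```r
testthat::test_dir("tests/testthat", package = "bondbreakr",
                   load_package = "installed")
```

## Worked example

```r
library(bondbreakr)

ethane <- parse_molecule("CC", "ethane")
start  <- embed_geometry(ethane, seed = 0)     # deterministic ETKDG conformer
unique_bonds(ethane)[, c("a", "b", "class_size")]
#>   a b class_size
#> 1 1 2          1      # the C-C bond
#> 2 1 3          6      # all six C-H bonds, one class

calc <- toy_forcefield(ethane, start)          # calibrated analytic toy FF
traj <- run_bond_trajectory(ethane, start, c(1, 2), calc,
                            sampler_config(rng_seed = 1))
traj
#> <trajectory_result> ethane bond 1-2: 15 opt + 150 md conformers (0 discarded)

records <- collect_records(traj, calc)         # label with E, F, dipole, N_FOD
man <- write_dataset(records, "ethane-cc", discarded_count = traj$discarded_count)
str(man[c("n_total", "n_opt", "n_md")])
#> List of 3
#>  $ n_total: int 165
#>  $ n_opt  : int 15
#>  $ n_md   : int 150

label_geometry(traj$opt_geometries[[1]], calc)$n_fod_by_temperature
#>            0         1000         5000
#> 0.000000e+00 8.412417e-16 2.914387e-03
label_geometry(traj$opt_geometries[[15]], calc)$n_fod_by_temperature
#>        0     1000     5000
#> 0.000000 1.688929 1.937319
```

The N<sub>FOD</sub> values show the point of the workflow: at the first
elongation step the molecule is still a gapped closed shell (N_FOD ≈ 0 at
every temperature), while at the final step (3× the equilibrium C–C
length) the mock HOMO–LUMO gap has nearly closed and the 5000 K
occupations approach the separated-biradical limit of 2 — the 0 K label
still reports a closed shell, which is why finite-temperature smearing is
used for labelling in the first place.

A thin CLI wraps the same functions
(`inst/scripts/bondbreakr <prepare|bonds|sample|evaluate> ...`).

## Package layout

| Path | Contents |
| --- | --- |
| `R/molecule.R`, `R/bridge.R` | SMILES parsing, filters, seeded 3D embedding (RDKit bridge) |
| `R/bondhash.R` | atom / neighbourhood / bond hashes, bond deduplication |
| `R/schedule.R`, `R/optimize.R`, `R/md.R`, `R/sampler.R` | elongation schedule, constrained optimization and NVT MD, the sampling loop |
| `R/diversity.R` | descriptors and greedy minimax selection |
| `R/electronic.R` | Fermi–Dirac occupations, N_FOD, labelling |
| `R/toy_models.R` | toy force field, mock spectrum, fixture suite |
| `R/datasetio.R` | dataset container, manifest, extended XYZ |
| `R/evaluate.R` | reaction energetics and MAE reports |
| `vignettes/bond-breaking-workflow.Rmd` | methods description and design rationale |
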