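---
title: "Sampling bond-breaking conformers for reactive potential training"
author: "bondbreakr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling bond-breaking conformers for reactive potential training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Machine-learned interatomic potentials trained on near-equilibrium
conformers extrapolate poorly into the regions that matter for reactivity:
stretched bonds, emerging radicals, rearranging fragments. `bondbreakr`
implements an automated workflow that manufactures exactly those
configurations for small organic molecules (H, C, N, O; at most seven heavy
atoms by default). For every chemically distinct bond of an input molecule
it:

1. stretches the bond stepwise through a staged elongation schedule,
2. after each step relaxes the rest of the molecule with the bond atoms
   constrained (so rearrangements such as hydrogen transfer can happen),
3. runs constrained NVT molecular dynamics and keeps a diverse subset of
   snapshots,
4. labels every kept conformer with energy, forces, dipole, and the
   finite-temperature radical-character measure N~FOD~.

With the default configuration each bond contributes 15 optimization
conformers plus 15 × 10 MD conformers = 165 labelled geometries.

```{r, eval = FALSE}
library(bondbreakr)

ethane <- parse_molecule("CC", "ethane")
start  <- embed_geometry(ethane, seed = 0)
calc   <- toy_forcefield(ethane, start)
traj   <- run_bond_trajectory(ethane, start, c(1, 2), calc,
                              sampler_config(rng_seed = 1))
records <- collect_records(traj, calc)
write_dataset(records, "ethane-cc")
```

## Bond deduplication: the bond-environment hash

The four C–H bonds of methane are chemically identical; sampling each would
quadruple the cost for no information. Bonds are therefore grouped by a
cheap environment descriptor:

* the **atom hash** is the 5-vector (atomic number, bonded hydrogens,
  bonded neighbours, total valence, aromatic flag);
* the **R~n~-atom hash** is the component-wise sum of the atom hashes of
  the atom and every atom within R~n~ = 3 bonds of it (breadth-first
  topological distance, closed neighbourhood);
* the **bond hash** is the sum of the two endpoint R~3~-atom hashes —
  symmetric in the endpoints and invariant under atom relabeling, a
  bond-centred relative of the Morgan fingerprint.

The hash is deliberately weaker than full graph canonization: bonds in one
automorphism orbit always share a hash, but the converse can fail. One
failure mode matters in practice and is corrected here: **in a molecule
smaller than the hash radius every atom's neighbourhood is the whole
molecule**, so all R~3~ sums coincide and, e.g., ethane's C–C bond would
merge with its C–H bonds. `unique_bonds()` therefore keys equivalence
classes on the bond hash *augmented with the sorted pair of endpoint
(radius-0) atom hashes*. The augmentation strictly refines the partition
and cannot split an orbit, because the endpoint atom hashes are themselves
isomorphism invariants. On 2,2-dimethylbutane the resulting classes agree
exactly with the graph-automorphism bond orbits (the test suite checks
this against an independent BLISS-based oracle).

Deduplication is cross-molecule by default (`scope = "global"`), with a
per-molecule mode for workflows that want one trajectory per bond per
molecule regardless of duplicates elsewhere.

## The elongation schedule

A bond of equilibrium length $l_0$ is driven through absolute targets
generated stage by stage; a stage $(n_e, n_\mathrm{steps})$ advances from
the previous endpoint to $n_e\,l_0$ in equal increments of
$l_\mathrm{step} = (n_e - 1)\,l_0 / n_\mathrm{steps}$ (single-stage case).
The default — 10 steps to $2\,l_0$, then 5 steps to $3\,l_0$ — concentrates
samples in the 1–2 bond-length range where rearrangements and radical
formation mostly happen. Endpoints are exact: `targets[10]/l0` is
bit-identical to 2 and `targets[15]/l0` to 3, because the last in-stage
fraction is computed as `n/n`.

Elongation displaces the two bond atoms symmetrically (±half the change
along the bond axis), preserving the pair midpoint and every other
coordinate bit-for-bit. The paper-style loop continues each step from the
previous step's *optimized* geometry (deterministic default); a flag
switches to continuing from the last MD frame.

## Constrained optimization and dynamics

Both bond atoms are held at **fixed Cartesian positions** during
optimization and MD (the workflow's reading of "positions of the atoms in
the selected bond fixed"); a distance-only constraint mode (SHAKE/RATTLE
projection, FIRE descent) is available behind
`sampler_config(constraint = "distance")`.

* *Optimization*: L-BFGS-B over the free coordinates, converged when the
  largest per-atom force norm on free atoms is ≤ `opt_fmax`
  (default 0.05 eV/Å, ≤ 500 iterations). Fixed rows of the coordinate
  matrix are never touched, so they are returned bit-identical.
* *Dynamics*: the technical MD settings are not prescribed by the sampling
  scheme itself, so they are explicit configuration with documented
  defaults: Langevin thermostat (BAOAB splitting) at 300 K, friction
  0.01 fs⁻¹, velocity Verlet core, 1 ps at dt = 0.5 fs, snapshots every
  10 fs (100 per segment). Velocities are initialized Maxwell–Boltzmann at
  the target temperature from a per-step seed derived as
  `rng_seed + 1000 · step`, with fixed atoms at zero velocity. With the
  thermostat disabled the integrator is plain velocity Verlet; the test
  suite verifies total-energy drift below 1% of the initial kinetic energy
  over 1 ps on the toy calculator.

Units follow the eV / Å / fs / amu convention throughout
(1 eV Å⁻¹ amu⁻¹ = 9.648533 × 10⁻³ Å fs⁻², k~B~ = 8.617333 × 10⁻⁵ eV/K).

A calculator is any object built with `new_calculator()` that returns
energy, forces, and optionally a dipole and a spin-orbital spectrum.
Failures must be *signalled* (`calculator_failure()`), never returned as
NaN; the sampling loop converts them into discarded geometries or cut MD
segments, mirroring how non-converged quantum-chemistry labels are dropped
from production datasets, and reports the counts.

## Diverse snapshot selection

Each 100-snapshot MD segment is reduced to at most `snapshot_cap = 10`
snapshots by greedy farthest-point ("minimax") selection. The descriptor
is the sorted vector of all pairwise interatomic distances — cheap,
alignment-free, and invariant under rotation, translation and atom
relabeling; the metric is Euclidean. Selection seeds with the earliest
snapshot and repeatedly adds the candidate whose minimum distance to the
chosen set is largest, ties broken by the smaller index — deterministic by
construction. The exact max–min subset optimum is *not* attempted; the
greedy per-step optimality property (each addition maximizes the minimum
distance among remaining candidates) is the documented semantic and is
asserted in the tests. Descriptor and metric were design choices; both
would be easy to swap behind the same interface.

## Finite-temperature occupations and N~FOD~

Conformers are labelled with fractional occupation (FO) numbers from the
Fermi–Dirac distribution over spin orbitals (each level holds at most one
electron). For T~el~ > 0 the Fermi energy is found by bisection until the
occupations sum to the electron count (tolerance 10⁻¹²; the spec-level
guarantee is 10⁻⁸). At T~el~ = 0 occupations are a step function,
degenerate levels at the cut share the remaining electrons equally, and a
gapped filling puts E~F~ mid-gap.

N~FOD~ is computed in occupation space:

$$N_\mathrm{FOD} \;=\; \sum_{\varepsilon_i < E_F} (1 - f_i)
  \;+\; \sum_{\varepsilon_i \ge E_F} f_i ,$$

which is the orthonormal-orbital reduction of the real-space integral of
the fractional orbital density (grid-based FOD maps are out of scope).
Levels within 10⁻⁹ energy units of E~F~ count as "not below": this makes
the separated-biradical limit — two electrons shared by a doubly
degenerate (four spin-level) frontier manifold pinned at E~F~, each with
f = ½ — give exactly 2 at any positive temperature. A closed shell with a
gap gives 0 as T~el~ → 0, and N~FOD~ at 0 K never exceeds its value at
5000 K. The spin-orbital convention is self-consistent and documented
here; FOD literature conventions differ by factors of two in how spatial
versus spin orbitals are counted.

The recommended electronic temperature follows the adopted affine
convention T~el~/K = 5000 + 20000 · a~x~, where a~x~ is the functional's
Fock-exchange fraction; a~x~ = 0 gives the 5000 K used for GGA-type
functionals. Labels default to T~el~ ∈ {0, 1000, 5000} K.

## The toy calculator

`toy_forcefield()` is a first-class, fully tested stand-in calculator:
harmonic bonds and angles plus exponential repulsion between atoms more
than two bonds apart, with exact analytic gradients (verified against
central finite differences to 10⁻⁴). Calibrating its equilibrium values
from the embedded geometry makes that geometry an exact minimum of the
bonded terms, avoiding large constraint forces at the first elongation
step. Its mock spectrum assigns each localized bond a filled
bonding/empty antibonding pair of spin levels; the sampled bond's
splitting decays as $g_0 e^{-(r - r_0)/w}$ (defaults $g_0$ = 8 eV,
$w$ = 0.6 Å), so the HOMO–LUMO gap closes and N~FOD~ rises monotonically
toward 2 as the bond stretches — emulating homolytic dissociation.

What the toy model does **not** emulate: reactivity. Bond topology never
changes, so rearrangements (hydrogen transfer, radical quenching) that a
real electronic-structure backend would produce are outside what passing
tests demonstrate. The toy dipole uses fixed neutrality-shifted
per-element charges; it is a plumbing check, not chemistry.

## Parsing and embedding

SMILES parsing and 3D embedding are delegated to RDKit through a bundled
Python bridge (`inst/python/mol_bridge.py`, requires `python` with RDKit
on the PATH). Two reasons: the atom-hash fields are defined in terms of
RDKit's atom properties, and RDKit's ETKDG embedder takes an explicit
random seed, giving the bit-identical reproducibility the workflow
promises — the same SMILES and seed always produce identical coordinates.
Hydrogens are always made explicit before hashing or sampling (the
workflow stretches C–H bonds). One conformer is embedded per molecule;
molecules with stereocenters are embedded as-is without stereoisomer
enumeration. Charged or radical SMILES parse but are rejected by the
default neutral-closed-shell validity check (`require_neutral = FALSE`
overrides). Bridge results are cached per session and batched per call.

## Dataset layout

`write_dataset()` produces a directory:

* `manifest.json` — totals, per-origin (`opt`/`md`) counts, discard count,
  declared units (eV, Å), per-molecule/bond accounting;
* `records.json` — the hierarchical container, grouped molecule → bond →
  step, serialized at full double precision (round trips are lossless
  well beyond the declared 10⁻⁸ Å / 10⁻¹⁰ eV);
* `frames.extxyz` — flat extended-XYZ export whose comment lines carry
  provenance and labels as key=value pairs.

Every record keeps full provenance: molecule id, bond, elongation step,
origin (`opt` or `md`), snapshot index, step target distance, stage, and
convergence flag. `read_dataset()` validates on load and reports malformed
records by index; reading traverses the hierarchy, so consumers needing
the original flat order should match records by provenance.

## Reaction energetics

`reaction_energetics()` returns P−R (reaction energy), TS−R (barrier
height) and TS−P for a reactant/transition-state/product triple, with the
cycle identity TS−R = P−R + TS−P exact by construction. `bde()` is the sum
of fragment energies minus the reactant energy; `mae_report()` aggregates
mean absolute errors per group and overall. These operate on energies
only, so they apply to any model's outputs; reproducing published
benchmark errors would require a trained potential and external benchmark
sets, which is deliberately out of scope.

## Problem sizes and determinism

The test and acceptance workloads use one full default run on ethane's
C–C bond (165 conformers, under a minute on one CPU) plus small
reduced-schedule runs for failure-path and determinism checks; these sizes
were chosen as the smallest cases that exercise every code path at the
workflow's standard conditions. All randomness — embedding, velocity
initialization, thermostat noise, fixture generation — flows from explicit
seeds, and identical inputs with identical seeds reproduce saved conformer
counts and coordinates bit-for-bit.

## Known limitations

* The hash is not a canonical-labeling equivalence: distinct orbits can
  still merge in larger molecules (by design, matching the descriptor's
  purpose of cheap deduplication).
* The bundled calculator cannot react; end-to-end tests demonstrate
  workflow mechanics, not chemistry.
* Periodic systems, multi-molecule boxes, transition-state search and
  IRC following are out of scope.
* MD temperature/thermostat defaults are package choices, exposed in
  `sampler_config()` precisely because no canonical values exist for the
  sampling scheme itself.
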