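# Bundled analytic toy force field and mock orbital-spectrum model. The toy
# calculator stands behind the calculator contract so the full sampling
# workflow runs and is testable without a quantum-chemistry backend; it is
# deliberately non-reactive (harmonic bonds never break topologically).

.toy_r0 <- c("H-H" = 0.74, "C-H" = 1.09, "H-N" = 1.01, "H-O" = 0.96,
             "C-C" = 1.53, "C-N" = 1.47, "C-O" = 1.43, "N-N" = 1.45,
             "N-O" = 1.40, "O-O" = 1.48)

toy_default_r0 <- function(el_a, el_b, order) {
  key <- paste(sort(c(el_a, el_b)), collapse = "-")
  r0 <- if (key %in% names(.toy_r0)) .toy_r0[[key]] else 1.5
  scale <- if (order >= 3) 0.81 else if (order >= 2) 0.87 else if (order > 1) 0.93 else 1.0
  r0 * scale
}

#' Mock spin-orbital spectrum with a bond-stretch-closing gap
#'
#' Emulates homolytic dissociation for testing occupation analysis: each of
#' `n_bonds` localized bonds contributes a filled bonding pair and an empty
#' antibonding pair of spin levels; the reference bond's bonding/antibonding
#' splitting decays exponentially as the bond stretches past its equilibrium
#' length, so the HOMO-LUMO gap closes and two electrons end up shared by
#' four near-degenerate frontier levels (N_FOD -> 2).
#'
#' @param n_bonds number of localized bonds in the model.
#' @param r current reference-bond length (Angstrom).
#' @param r0 equilibrium reference-bond length (Angstrom).
#' @param gap0 frontier gap at equilibrium (eV, default 8).
#' @param width gap decay length (Angstrom, default 0.6).
#' @param deep |energy| of the non-reference bonding/antibonding levels (eV).
#' @return list with `energies` (sorted spin-orbital energies, eV) and
#'   `n_electrons` (= 2 * n_bonds; each spin level holds one electron).
#' @export
toy_spectrum <- function(n_bonds, r, r0, gap0 = 8, width = 0.6, deep = 6) {
  stopifnot(n_bonds >= 1)
  gap <- gap0 * exp(-max(r - r0, 0) / width)
  e <- c(rep(-deep, 2L * (n_bonds - 1L)), rep(-gap / 2, 2L),
         rep(gap / 2, 2L), rep(deep, 2L * (n_bonds - 1L)))
  list(energies = sort(e), n_electrons = 2L * n_bonds)
}

toy_partial_charges <- function(elements) {
  q <- c(H = 0.10, C = -0.10, N = -0.35, O = -0.45)[elements]
  q[is.na(q)] <- 0
  unname(q - mean(q))
}

#' Analytic toy force field implementing the calculator contract
#'
#' Harmonic bond and angle terms plus an exponential repulsion between
#' atom pairs more than two bonds apart. Energy is in eV, coordinates in
#' Angstrom; forces are the exact analytic negative gradient. When a
#' reference `geometry` is supplied (the recommended use: pass the embedded
#' equilibrium conformer) the equilibrium bond lengths and angles are taken
#' from it, so all bond and angle terms vanish there and the geometry is an
#' exact zero-energy minimum whenever no atom pair lies more than two bonds
#' apart (with `rep_a = 0`, always); otherwise tabulated per-element-pair
#' defaults are used.
#'
#' The calculator also reports a dipole from fixed, neutrality-shifted
#' per-element partial charges and a mock spin-orbital spectrum
#' ([toy_spectrum()]) whose reference bond is the evaluated geometry's
#' provenance bond (falling back to `spectrum_bond`, then the first bond),
#' so radical character grows as the sampled bond stretches.
#'
#' @param record a `molecule_record` declaring the connectivity.
#' @param geometry optional reference `bb_geometry` used to calibrate
#'   equilibrium bond lengths and angles.
#' @param k_bond bond force constant (eV / Angstrom^2).
#' @param k_angle angle force constant (eV / rad^2).
#' @param rep_a,rep_rho nonbonded repulsion amplitude (eV) and length
#'   scale (Angstrom).
#' @param spectrum_bond default reference bond `c(a, b)` for the mock
#'   spectrum.
#' @param gap0,gap_width mock-spectrum gap at equilibrium (eV) and decay
#'   length (Angstrom).
#' @param fail_if optional predicate `function(geometry)`; evaluation raises
#'   a calculator failure when it returns TRUE (used to exercise the
#'   discard path).
#' @return a `bb_calculator` with capabilities energy, forces, dipole and
#'   orbital_energies.
#' @export
toy_forcefield <- function(record, geometry = NULL, k_bond = 25, k_angle = 3,
                           rep_a = 4, rep_rho = 0.35, spectrum_bond = NULL,
                           gap0 = 8, gap_width = 0.6, fail_if = NULL) {
  bonds <- record$bonds
  n <- length(record$elements)

  r0 <- vapply(seq_len(nrow(bonds)), function(i) {
    if (!is.null(geometry)) {
      atom_distance(geometry, bonds$a[i], bonds$b[i])
    } else {
      toy_default_r0(record$elements[bonds$a[i]], record$elements[bonds$b[i]],
                     bonds$order[i])
    }
  }, 1.0)

  # angle triples i-j-k for every pair of neighbours of each centre j
  adj <- lapply(seq_len(n), function(i) {
    sort(c(bonds$b[bonds$a == i], bonds$a[bonds$b == i]))
  })
  angles <- do.call(rbind, lapply(seq_len(n), function(j) {
    nb <- adj[[j]]
    if (length(nb) < 2) return(NULL)
    cmb <- utils::combn(nb, 2)
    data.frame(i = cmb[1, ], j = j, k = cmb[2, ])
  }))
  theta0 <- if (is.null(angles)) numeric(0) else {
    vapply(seq_len(nrow(angles)), function(t) {
      if (!is.null(geometry)) {
        angle_value(geometry$coords, angles$i[t], angles$j[t], angles$k[t])
      } else if (record$aromatic[angles$j[t]]) 2 * pi / 3 else 1.9106332362490186
    }, 1.0)
  }

  topo <- topo_distances(record)
  nb_pairs <- which(upper.tri(topo) & (topo > 2), arr.ind = TRUE)

  masses_q <- toy_partial_charges(record$elements)

  ref_bond_default <- if (!is.null(spectrum_bond)) {
    as.integer(spectrum_bond)
  } else if (nrow(bonds) > 0) {
    c(bonds$a[1], bonds$b[1])
  } else {
    NULL
  }

  evaluate <- function(geom) {
    if (!is.null(fail_if) && isTRUE(fail_if(geom))) {
      calculator_failure("injected toy-calculator failure")
    }
    x <- geom$coords
    e <- 0
    g <- matrix(0, nrow(x), 3)

    for (t in seq_len(nrow(bonds))) {
      a <- bonds$a[t]; b <- bonds$b[t]
      dv <- x[a, ] - x[b, ]
      r <- sqrt(sum(dv^2))
      de <- k_bond * (r - r0[t])
      e <- e + 0.5 * k_bond * (r - r0[t])^2
      gr <- de * dv / r
      g[a, ] <- g[a, ] + gr
      g[b, ] <- g[b, ] - gr
    }

    if (!is.null(angles)) {
      for (t in seq_len(nrow(angles))) {
        ai <- angles$i[t]; aj <- angles$j[t]; ak <- angles$k[t]
        u <- x[ai, ] - x[aj, ]
        v <- x[ak, ] - x[aj, ]
        nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
        cth <- min(max(sum(u * v) / (nu * nv), -1), 1)
        th <- acos(cth)
        sth <- max(sqrt(1 - cth^2), 1e-8)
        e <- e + 0.5 * k_angle * (th - theta0[t])^2
        pref <- -k_angle * (th - theta0[t]) / sth
        dci <- v / (nu * nv) - cth * u / nu^2
        dck <- u / (nu * nv) - cth * v / nv^2
        g[ai, ] <- g[ai, ] + pref * dci
        g[ak, ] <- g[ak, ] + pref * dck
        g[aj, ] <- g[aj, ] - pref * (dci + dck)
      }
    }

    if (nrow(nb_pairs) > 0) {
      for (t in seq_len(nrow(nb_pairs))) {
        a <- nb_pairs[t, 1]; b <- nb_pairs[t, 2]
        dv <- x[a, ] - x[b, ]
        r <- sqrt(sum(dv^2))
        e <- e + rep_a * exp(-r / rep_rho)
        gr <- -(rep_a / rep_rho) * exp(-r / rep_rho) * dv / r
        g[a, ] <- g[a, ] + gr
        g[b, ] <- g[b, ] - gr
      }
    }

    ref <- geom$provenance$bond
    if (length(ref) != 2 || any(is.na(ref))) ref <- ref_bond_default
    spectrum <- NULL
    if (!is.null(ref) && nrow(bonds) > 0) {
      t_ref <- which(bonds$a == min(ref) & bonds$b == max(ref))
      r0_ref <- if (length(t_ref) == 1) r0[t_ref] else 1.5
      r_ref <- sqrt(sum((x[ref[1], ] - x[ref[2], ])^2))
      spectrum <- toy_spectrum(max(nrow(bonds), 1L), r_ref, r0_ref,
                               gap0 = gap0, width = gap_width)
    }

    list(energy = e, forces = -g,
         dipole = as.numeric(colSums(masses_q * x)),
         orbitals = spectrum)
  }

  new_calculator(evaluate,
                 capabilities = c("energy", "forces", "dipole",
                                  "orbital_energies"),
                 units = c(energy = "eV", length = "angstrom"),
                 label = sprintf("toy force field (%s)", record$identifier))
}

angle_value <- function(x, i, j, k) {
  u <- x[i, ] - x[j, ]
  v <- x[k, ] - x[j, ]
  acos(min(max(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1))
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

random_tree_smiles <- function(n_heavy) {
  caps <- c(C = 4L, N = 3L, O = 2L)
  repeat {
    elems <- sample(names(caps), n_heavy, replace = TRUE,
                    prob = c(0.6, 0.2, 0.2))
    remaining <- unname(caps[elems])
    parent <- integer(n_heavy)
    ok <- TRUE
    for (i in seq_len(n_heavy)[-1]) {
      avail <- which(remaining[seq_len(i - 1)] > 0)
      if (!length(avail)) { ok <- FALSE; break }
      p <- if (length(avail) == 1) avail else sample(avail, 1)
      parent[i] <- p
      remaining[p] <- remaining[p] - 1L
      remaining[i] <- remaining[i] - 1L
    }
    if (ok) break
  }
  kids <- lapply(seq_len(n_heavy), function(i) which(parent == i))
  build <- function(i) {
    sub <- vapply(kids[[i]], function(c) paste0("(", build(c), ")"), "")
    paste0(elems[i], paste(sub, collapse = ""))
  }
  build(1)
}

#' Deterministic fixture suite of molecules and geometries
#'
#' Bundles the worked species of the workflow (methane, ethane,
#' 2,2-dimethylbutane, 1-aminoethanol, ethanimine) together with seeded
#' random acyclic H/C/N/O molecules of at most seven heavy atoms, all
#' parsed and (optionally) embedded. The same seed always yields an
#' identical bundle.
#'
#' @param seed integer seed controlling the random molecules and embedding.
#' @param n_random number of random molecules to add.
#' @param embed also embed every molecule (default TRUE).
#' @return list with `records` (named list of `molecule_record`),
#'   `geometries` (named list of `bb_geometry`, if `embed`), and `table`
#'   (data.frame identifier/smiles).
#' @export
make_fixture_suite <- function(seed = 0L, n_random = 5L, embed = TRUE) {
  named <- c(methane = "C", ethane = "CC", dimethylbutane = "CCC(C)(C)C",
             aminoethanol = "CC(N)O", ethanimine = "CC=N")
  rand <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      random_tree_smiles(sample(2:7, 1))
    }, "")
  })
  names(rand) <- sprintf("random%02d", seq_len(n_random))
  smiles <- c(named, rand)
  ids <- names(smiles)

  # one batched bridge call warms the cache for parse and embed
  qs <- lapply(unname(smiles), function(s) list(smiles = s, embed = FALSE, seed = 0L))
  if (embed) {
    qs <- c(qs, lapply(unname(smiles), function(s) {
      list(smiles = s, embed = TRUE, seed = as.integer(seed))
    }))
  }
  rdkit_query(qs)

  records <- parse_molecules(unname(smiles), ids)
  out <- list(records = records,
              table = data.frame(identifier = ids, smiles = unname(smiles),
                                 stringsAsFactors = FALSE))
  if (embed) {
    out$geometries <- lapply(records, embed_geometry, seed = seed)
  }
  out
}
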