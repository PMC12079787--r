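# Shared fixtures. Expensive objects (parsed molecules, embeddings, the
# full default ethane C-C run) are computed once per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- make()
  .fixture_env[[name]]
}

ethane_record <- function() fixture("ethane_rec", function() parse_molecule("CC", "ethane"))
ethane_geom <- function() fixture("ethane_geom", function() embed_geometry(ethane_record(), seed = 0))
ethane_calc <- function() fixture("ethane_calc", function() toy_forcefield(ethane_record(), ethane_geom()))

methane_record <- function() fixture("methane_rec", function() parse_molecule("C", "methane"))

# Complete default workflow run on ethane's C-C bond (the workflow's
# standard accounting case); reused by several tests.
ethane_cc_run <- function() {
  fixture("ethane_cc_run", function() {
    run_bond_trajectory(ethane_record(), ethane_geom(), c(1, 2),
                        ethane_calc(), sampler_config(rng_seed = 1))
  })
}

# A harmonic-bond-only calculator for analytic optimizer oracles: atoms are
# bonded as given with unit equilibrium length and force constant k.
harmonic_calculator <- function(bonds, k = 10, r0 = 1) {
  new_calculator(function(geom) {
    x <- geom$coords
    e <- 0
    g <- matrix(0, nrow(x), 3)
    for (t in seq_len(nrow(bonds))) {
      a <- bonds[t, 1]; b <- bonds[t, 2]
      dv <- x[a, ] - x[b, ]
      r <- sqrt(sum(dv^2))
      e <- e + 0.5 * k * (r - r0)^2
      gr <- k * (r - r0) * dv / r
      g[a, ] <- g[a, ] + gr
      g[b, ] <- g[b, ] - gr
    }
    list(energy = e, forces = -g)
  }, label = "harmonic oracle")
}

# Graph-automorphism bond orbits (BLISS generators + closure): the
# independent oracle for bond-equivalence soundness.
bond_orbits <- function(record) {
  g <- igraph::graph_from_edgelist(as.matrix(record$bonds[, c("a", "b")]),
                                   directed = FALSE)
  gens <- lapply(igraph::automorphism_group(
    g, colors = as.integer(factor(record$elements))), as.integer)
  key <- function(a, b) paste(min(a, b), max(a, b))
  bk <- mapply(key, record$bonds$a, record$bonds$b)
  orbit <- seq_along(bk)
  repeat {
    changed <- FALSE
    for (p in gens) for (i in seq_along(bk)) {
      j <- match(key(p[record$bonds$a[i]], p[record$bonds$b[i]]), bk)
      lo <- min(orbit[i], orbit[j])
      if (orbit[i] != lo || orbit[j] != lo) {
        orbit[orbit == orbit[i] | orbit == orbit[j]] <- lo
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  orbit
}

# Apply a relabeling permutation to a molecule record (perm[i] = new index
# of old atom i), used for permutation-invariance properties.
relabel_record <- function(record, perm) {
  inv <- order(perm)
  bonds <- record$bonds
  a2 <- perm[bonds$a]; b2 <- perm[bonds$b]
  bonds$a <- pmin(a2, b2); bonds$b <- pmax(a2, b2)
  bonds <- bonds[order(bonds$a, bonds$b), , drop = FALSE]
  rownames(bonds) <- NULL
  record$elements <- record$elements[inv]
  record$explicit_h_counts <- record$explicit_h_counts[inv]
  record$valences <- record$valences[inv]
  record$formal_charges <- record$formal_charges[inv]
  record$aromatic <- record$aromatic[inv]
  record$radical_electrons <- record$radical_electrons[inv]
  record$bonds <- bonds
  record
}
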