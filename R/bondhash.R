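# Bond-environment hashing: a bond-centred relative of the Morgan
# fingerprint used to collapse chemically equivalent bonds so the sampling
# workflow runs once per equivalence class.

.element_z <- c(H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L,
                O = 8L, F = 9L, Ne = 10L, Na = 11L, Mg = 12L, Al = 13L,
                Si = 14L, P = 15L, S = 16L, Cl = 17L, Ar = 18L, K = 19L,
                Ca = 20L, Br = 35L, I = 53L)

atomic_number <- function(symbol) {
  z <- .element_z[symbol]
  if (any(is.na(z))) {
    stop("unknown element symbol: ", paste(symbol[is.na(z)], collapse = ", "),
         call. = FALSE)
  }
  unname(z)
}

#' Atomic environment descriptor (atom hash)
#'
#' Five integers describing an atom: atomic number, number of bonded
#' hydrogens, number of bonded neighbours, total valence, and an aromatic
#' indicator (0/1).
#'
#' @param record a `molecule_record` (hydrogens explicit).
#' @param atom_index 1-based atom index.
#' @return named integer vector of length 5.
#' @export
atom_hash <- function(record, atom_index) {
  n <- length(record$elements)
  if (atom_index < 1L || atom_index > n) {
    stop("atom_index out of range", call. = FALSE)
  }
  deg <- sum(record$bonds$a == atom_index | record$bonds$b == atom_index)
  c(atomic_number = atomic_number(record$elements[atom_index]),
    n_hydrogens = record$explicit_h_counts[atom_index],
    n_neighbors = as.integer(deg),
    valence = record$valences[atom_index],
    aromatic = as.integer(record$aromatic[atom_index]))
}

bond_graph <- function(record) {
  n <- length(record$elements)
  if (nrow(record$bonds) == 0) {
    return(igraph::make_empty_graph(n, directed = FALSE))
  }
  igraph::graph_from_edgelist(as.matrix(record$bonds[, c("a", "b")]),
                              directed = FALSE)
}

topo_distances <- function(record) {
  igraph::distances(bond_graph(record))
}

#' Neighbourhood atom hash (R_n-atom hash)
#'
#' Component-wise sum of the atom hashes of the atom itself and every atom
#' within `radius` bonds of it (breadth-first topological distance).
#'
#' @inheritParams atom_hash
#' @param radius neighbourhood radius in bonds (>= 0); the workflow default
#'   is 3.
#' @return named integer vector of length 5.
#' @export
rn_atom_hash <- function(record, atom_index, radius = 3L) {
  if (radius < 0L) stop("radius must be >= 0", call. = FALSE)
  d <- topo_distances(record)[atom_index, ]
  idx <- which(d <= radius)
  h <- vapply(idx, function(i) atom_hash(record, i), integer(5))
  out <- as.integer(rowSums(h))
  names(out) <- rownames(h)
  out
}

#' Bond-environment hash
#'
#' The sum of the radius-3 neighbourhood atom hashes of the two atoms
#' forming the bond. Symmetric in the two atoms and invariant under atom
#' relabeling; bonds sharing a hash are treated as chemically equivalent.
#'
#' @inheritParams atom_hash
#' @param bond integer vector `c(a, b)`; must be a bond of the record.
#' @param radius neighbourhood radius (default 3).
#' @return named integer vector of length 5.
#' @export
bond_hash <- function(record, bond, radius = 3L) {
  a <- min(bond); b <- max(bond)
  if (!any(record$bonds$a == a & record$bonds$b == b)) {
    stop(sprintf("atoms %d-%d are not bonded", a, b), call. = FALSE)
  }
  rn_atom_hash(record, a, radius) + rn_atom_hash(record, b, radius)
}

hash_key <- function(h) paste(h, collapse = "|")

bond_hash_table <- function(record, radius = 3L) {
  bonds <- record$bonds
  if (nrow(bonds) == 0) {
    return(data.frame(identifier = character(), a = integer(), b = integer(),
                      key = character(), stringsAsFactors = FALSE))
  }
  d <- topo_distances(record)
  a0 <- vapply(seq_along(record$elements), function(i) atom_hash(record, i),
               integer(5))
  rn <- vapply(seq_along(record$elements), function(i) {
    rowSums(a0[, d[i, ] <= radius, drop = FALSE])
  }, numeric(5))
  # class key: R3 bond hash augmented with the sorted endpoint atom-hash
  # pair, so bonds between chemically different atom types never merge even
  # when the radius-3 neighbourhoods cover the whole molecule
  keys <- vapply(seq_len(nrow(bonds)), function(i) {
    ends <- sort(c(hash_key(a0[, bonds$a[i]]), hash_key(a0[, bonds$b[i]])))
    paste(c(hash_key(as.integer(rn[, bonds$a[i]] + rn[, bonds$b[i]])), ends),
          collapse = ";")
  }, "")
  data.frame(identifier = record$identifier, a = bonds$a, b = bonds$b,
             key = keys, stringsAsFactors = FALSE)
}

#' Deduplicate chemically equivalent bonds by their bond hash
#'
#' Groups every bond of the input molecule(s) by its bond-environment hash
#' and keeps one representative per class: the lexicographically smallest
#' normalized `(a, b)` pair of the earliest molecule. By default hashes are
#' compared across the whole input set; `scope = "per_molecule"` restricts
#' classes to single molecules.
#'
#' The class key is the radius-3 bond hash augmented with the sorted pair
#' of endpoint (radius-0) atom hashes. The augmentation strictly refines
#' the partition and never splits a graph-automorphism orbit (endpoint
#' atom hashes are isomorphism invariants); it exists because in molecules
#' smaller than the hash radius the plain neighbourhood sums of all atoms
#' coincide, which would merge chemically different bonds (ethane's C-C
#' with its C-H) and defeat the purpose of sampling each distinct bond.
#'
#' @param records a `molecule_record` or list of them.
#' @param radius neighbourhood radius (default 3).
#' @param scope `"global"` (deduplicate across molecules) or
#'   `"per_molecule"`.
#' @return data.frame with one row per bond class: `identifier`, `a`, `b`
#'   (the representative bond), `key` (hash key), `class_size`. The full
#'   bond-to-class assignment is attached as attribute `"assignments"`.
#' @export
unique_bonds <- function(records, radius = 3L,
                         scope = c("global", "per_molecule")) {
  scope <- match.arg(scope)
  if (inherits(records, "molecule_record")) records <- list(records)
  tab <- do.call(rbind, lapply(records, bond_hash_table, radius = radius))
  if (is.null(tab) || nrow(tab) == 0) {
    out <- data.frame(identifier = character(), a = integer(), b = integer(),
                      key = character(), class_size = integer())
    attr(out, "assignments") <- tab
    return(out)
  }
  tab$mol_order <- match(tab$identifier, unique(tab$identifier))
  grp_key <- if (scope == "global") tab$key else paste(tab$identifier, tab$key)
  tab$class <- match(grp_key, unique(grp_key))
  reps <- do.call(rbind, lapply(split(tab, tab$class), function(g) {
    g <- g[order(g$mol_order, g$a, g$b), , drop = FALSE]
    data.frame(identifier = g$identifier[1], a = g$a[1], b = g$b[1],
               key = g$key[1], class_size = nrow(g), stringsAsFactors = FALSE)
  }))
  reps <- reps[order(match(reps$identifier, unique(tab$identifier)),
                     reps$a, reps$b), , drop = FALSE]
  rownames(reps) <- NULL
  attr(reps, "assignments") <- tab[, c("identifier", "a", "b", "key", "class")]
  reps
}
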