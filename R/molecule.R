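#' Parse a SMILES string into a connectivity-level molecule record
#'
#' Hydrogens are always made explicit: the sampling workflow stretches C-H
#' bonds and the bond hash must see them. Parsing is delegated to RDKit via
#' the bundled bridge; bond orders use RDKit's numeric convention (aromatic
#' bonds are order 1.5 with `aromatic = TRUE`).
#'
#' By default the record must describe a neutral closed-shell molecule
#' (no formal charges, no radical electrons), mirroring the stable small
#' organic molecules the workflow is designed for; set
#' `require_neutral = FALSE` to accept charged or radical inputs.
#'
#' @param smiles SMILES string.
#' @param identifier molecule identifier used in provenance and error
#'   messages; defaults to the SMILES itself.
#' @param require_neutral reject charged or radical molecules (default TRUE).
#' @return object of class `molecule_record` with fields `identifier`,
#'   `smiles`, `elements`, `bonds` (data.frame `a`, `b`, `order`, `aromatic`
#'   with `a < b`), `explicit_h_counts`, `valences`, `formal_charges`,
#'   `aromatic`, `radical_electrons`.
#' @examples
#' \dontrun{
#' rec <- parse_molecule("CC", "ethane")
#' nrow(rec$bonds)  # 7: one C-C and six C-H
#' }
#' @export
parse_molecule <- function(smiles, identifier = smiles, require_neutral = TRUE) {
  res <- rdkit_query(list(list(smiles = smiles, embed = FALSE, seed = 0L)))[[1]]
  if (!is.null(res$error)) {
    stop(sprintf("molecule '%s': %s", identifier, res$error), call. = FALSE)
  }
  rec <- record_from_bridge(res, identifier, smiles)
  if (require_neutral) {
    if (any(rec$formal_charges != 0L)) {
      stop(sprintf("molecule '%s' carries formal charge; pass require_neutral = FALSE to accept",
                   identifier), call. = FALSE)
    }
    if (any(rec$radical_electrons > 0L)) {
      stop(sprintf("molecule '%s' has radical electrons; pass require_neutral = FALSE to accept",
                   identifier), call. = FALSE)
    }
  }
  rec
}

record_from_bridge <- function(res, identifier, smiles) {
  elements <- vapply(res$elements, as.character, "")
  bonds <- do.call(rbind, lapply(res$bonds, function(b) {
    a <- as.integer(b[[1]]); bb <- as.integer(b[[2]])
    data.frame(a = min(a, bb), b = max(a, bb),
               order = as.numeric(b[[3]]), aromatic = isTRUE(b[[4]]))
  }))
  if (is.null(bonds)) {
    bonds <- data.frame(a = integer(), b = integer(), order = numeric(),
                        aromatic = logical())
  }
  bonds <- bonds[order(bonds$a, bonds$b), , drop = FALSE]
  rownames(bonds) <- NULL
  n <- length(elements)
  h_counts <- integer(n)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a[i]; b <- bonds$b[i]
    if (elements[b] == "H") h_counts[a] <- h_counts[a] + 1L
    if (elements[a] == "H") h_counts[b] <- h_counts[b] + 1L
  }
  structure(list(
    identifier = identifier,
    smiles = smiles,
    elements = elements,
    bonds = bonds,
    explicit_h_counts = h_counts,
    valences = vapply(res$valences, as.integer, 1L),
    formal_charges = vapply(res$formal_charges, as.integer, 1L),
    aromatic = vapply(res$aromatic, isTRUE, TRUE),
    radical_electrons = vapply(res$radical_electrons, as.integer, 1L)
  ), class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule_record> %s (%s): %d atoms, %d bonds, %d heavy\n",
              x$identifier, x$smiles, length(x$elements), nrow(x$bonds),
              sum(x$elements != "H")))
  invisible(x)
}

#' Element and size filter for workflow input molecules
#'
#' The sampling workflow targets small organic molecules: by default only
#' H, C, N and O are allowed and at most seven heavy (non-hydrogen) atoms.
#'
#' @param record a `molecule_record`.
#' @param allowed_elements permitted element symbols.
#' @param max_heavy maximum number of non-hydrogen atoms.
#' @return TRUE iff the record passes.
#' @export
passes_filter <- function(record, allowed_elements = c("H", "C", "N", "O"),
                          max_heavy = 7L) {
  all(record$elements %in% allowed_elements) &&
    sum(record$elements != "H") <= max_heavy
}

#' Embed a molecule record as a single 3D conformer
#'
#' Uses RDKit's seeded distance-geometry embedding (ETKDGv3): the same
#' record and seed always give bit-identical coordinates. One conformer is
#' produced per molecule.
#'
#' @param record a `molecule_record`.
#' @param seed integer random seed for the embedder.
#' @return a `bb_geometry` whose provenance carries the molecule identifier.
#' @export
embed_geometry <- function(record, seed = 0L) {
  res <- rdkit_query(list(list(smiles = record$smiles, embed = TRUE,
                               seed = as.integer(seed))))[[1]]
  if (!is.null(res$error)) {
    stop(sprintf("molecule '%s': %s", record$identifier, res$error),
         call. = FALSE)
  }
  elements <- vapply(res$elements, as.character, "")
  if (!identical(elements, record$elements)) {
    stop(sprintf("molecule '%s': embedder atom order does not match record",
                 record$identifier), call. = FALSE)
  }
  coords <- do.call(rbind, lapply(res$coords, function(p) as.numeric(unlist(p))))
  geom <- geometry(elements, coords,
                   provenance = list(molecule_id = record$identifier,
                                     origin = "start"))
  d <- bonded_distances(record, geom)
  if (any(d < 0.7 | d > 2.0)) {
    stop(sprintf("molecule '%s': embedded bond length outside [0.7, 2.0] A",
                 record$identifier), call. = FALSE)
  }
  geom
}

bonded_distances <- function(record, geom) {
  vapply(seq_len(nrow(record$bonds)), function(i) {
    atom_distance(geom, record$bonds$a[i], record$bonds$b[i])
  }, 1.0)
}

#' Read a molecule table (identifier + SMILES columns) from CSV
#'
#' @param path CSV file with columns `identifier` and `smiles`.
#' @return list of `molecule_record`.
#' @export
read_molecule_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("identifier", "smiles") %in% names(df))) {
    stop("molecule table needs 'identifier' and 'smiles' columns", call. = FALSE)
  }
  parse_molecules(df$smiles, df$identifier)
}

#' Parse many SMILES in one bridge call
#'
#' @param smiles character vector of SMILES.
#' @param identifiers matching identifiers.
#' @param require_neutral as in [parse_molecule()].
#' @return list of `molecule_record`.
#' @export
parse_molecules <- function(smiles, identifiers = smiles, require_neutral = TRUE) {
  qs <- lapply(smiles, function(s) list(smiles = s, embed = FALSE, seed = 0L))
  res <- rdkit_query(qs)
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    if (!is.null(res[[i]]$error)) {
      stop(sprintf("molecule '%s': %s", identifiers[i], res[[i]]$error),
           call. = FALSE)
    }
    out[[i]] <- record_from_bridge(res[[i]], identifiers[i], smiles[i])
    if (require_neutral &&
        (any(out[[i]]$formal_charges != 0L) || any(out[[i]]$radical_electrons > 0L))) {
      stop(sprintf("molecule '%s' is not neutral closed-shell", identifiers[i]),
           call. = FALSE)
    }
  }
  names(out) <- identifiers
  out
}
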