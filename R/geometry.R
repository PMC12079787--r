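#' Cartesian conformer with provenance
#'
#' A `bb_geometry` holds element symbols, an n x 3 coordinate matrix in
#' Angstrom, and a provenance record saying where in the sampling workflow
#' the conformer came from.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (n x 3), Angstrom.
#' @param provenance list with any of `molecule_id`, `bond` (length-2 integer),
#'   `step` (elongation step index), `origin` (`"opt"`, `"md"` or `"start"`),
#'   `snapshot` (snapshot index within an MD segment). Missing fields are NA.
#' @return object of class `bb_geometry`.
#' @export
geometry <- function(elements, coords, provenance = list()) {
  coords <- unname(as.matrix(coords))
  storage.mode(coords) <- "double"
  if (nrow(coords) != length(elements) || ncol(coords) != 3) {
    stop("coords must be a length(elements) x 3 matrix", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  prov <- list(molecule_id = NA_character_, bond = NA_integer_,
               step = NA_integer_, origin = NA_character_,
               snapshot = NA_integer_)
  for (nm in intersect(names(provenance), names(prov))) prov[[nm]] <- provenance[[nm]]
  structure(list(elements = as.character(elements), coords = coords,
                 provenance = prov),
            class = "bb_geometry")
}

#' @export
print.bb_geometry <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<bb_geometry> %d atoms (%s)\n", length(x$elements),
              paste(unique(x$elements), collapse = ",")))
  if (!is.na(p$molecule_id)) {
    cat(sprintf("  provenance: molecule=%s bond=%s step=%s origin=%s snapshot=%s\n",
                p$molecule_id, paste(p$bond, collapse = "-"), p$step, p$origin,
                p$snapshot))
  }
  invisible(x)
}

n_atoms <- function(geom) length(geom$elements)

#' Distance between two atoms of a geometry
#'
#' @param geom a `bb_geometry`.
#' @param a,b atom indices (1-based).
#' @return distance in Angstrom.
#' @export
atom_distance <- function(geom, a, b) {
  sqrt(sum((geom$coords[a, ] - geom$coords[b, ])^2))
}

with_provenance <- function(geom, ...) {
  upd <- list(...)
  for (nm in names(upd)) geom$provenance[[nm]] <- upd[[nm]]
  geom
}
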