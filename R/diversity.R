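# Diverse snapshot selection: greedy farthest-point ("minimax") subset
# selection on rotation/permutation-invariant geometry descriptors.

#' Snapshot descriptor: sorted pairwise interatomic distances
#'
#' Cheap alignment-free descriptor, invariant under rigid rotation,
#' translation and atom relabeling by construction.
#'
#' @param geom a `bb_geometry` with at least two atoms.
#' @return numeric vector of length n(n-1)/2, non-decreasing.
#' @export
describe_snapshot <- function(geom) {
  if (n_atoms(geom) < 2) stop("descriptor needs >= 2 atoms", call. = FALSE)
  sort(as.numeric(stats::dist(geom$coords)))
}

#' Greedy farthest-point (minimax) subset selection
#'
#' Selects up to `k` maximally diverse candidates. If there are at most `k`
#' candidates all are returned in order. Otherwise the selection is seeded
#' with the first candidate (earliest in time) and repeatedly adds the
#' candidate whose minimum Euclidean distance to the already-selected set
#' is largest, breaking ties by smallest index. This is the documented
#' greedy approximation; the exact max-min subset problem is not attempted.
#'
#' @param descriptors numeric matrix (one row per candidate) or list of
#'   equal-length numeric vectors.
#' @param k maximum number of selections (>= 1).
#' @return integer vector of selected candidate indices (1-based),
#'   deterministic for a given input order.
#' @export
minimax_select <- function(descriptors, k) {
  if (is.list(descriptors)) descriptors <- do.call(rbind, descriptors)
  n <- if (is.null(descriptors)) 0L else nrow(descriptors)
  if (n == 0L) return(integer(0))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (n <= k) return(seq_len(n))
  d <- unname(as.matrix(stats::dist(descriptors)))
  selected <- 1L
  min_d <- d[, 1L]
  while (length(selected) < k) {
    min_d[selected] <- -Inf
    best <- which.max(min_d)  # ties: smallest index
    selected <- c(selected, best)
    min_d <- pmin(min_d, d[, best])
  }
  as.integer(selected)
}
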