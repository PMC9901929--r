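#' Covalent radii used for bond detection
#'
#' Single-bond covalent radii (Angstrom) for the supported element set
#' (Cordero-style values).
#'
#' @return Named numeric vector.
#' @export
covalent_radii <- function() {
  c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, Na = 1.66, S = 1.05)
}

#' Build the bond graph of a structure
#'
#' Two atoms are bonded when their closest interatomic distance — including
#' symmetry images and lattice translations within one cell shell — is
#' below \eqn{r_i + r_j + tol}. Atoms belonging to two different disorder
#' parts (both `part > 0`, different ids) are never bonded.
#'
#' @param structure A [crystal_structure()].
#' @param radius_table Named numeric vector element -> covalent radius.
#' @param tolerance Additive distance tolerance in Angstrom.
#' @return A `bond_graph`: list with `bonds` (tibble `a`, `b`, `length`),
#'   `adjacency` (named list label -> character vector of neighbours) and
#'   `ring_atoms` (labels that sit in a ring of size 3-7).
#' @export
build_bond_graph <- function(structure, radius_table = covalent_radii(),
                             tolerance = 0.4) {
  stopifnot(inherits(structure, "crystal_structure"))
  at <- structure$atoms
  n <- nrow(at)
  if (n < 1) stop("build_bond_graph: structure has no atoms")
  miss <- setdiff(unique(at$element), names(radius_table))
  if (length(miss)) stop("build_bond_graph: no covalent radius for ", paste(miss, collapse = ", "))

  X <- t(as.matrix(at[, c("x", "y", "z")]))  # 3 x n fractional
  a_lab <- b_lab <- character(0)
  len <- numeric(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (at$part[i] > 0 && at$part[j] > 0 && at$part[i] != at$part[j]) next
      cutoff <- radius_table[at$element[i]] + radius_table[at$element[j]] + tolerance
      dmin <- Inf
      for (op in structure$symops) {
        xj <- apply_symop(op, X[, j])
        d <- frac_distance(structure$cell, X[, i], xj)
        if (d > 1e-6) dmin <- min(dmin, d)
      }
      if (dmin < cutoff) {
        a_lab <- c(a_lab, at$label[i]); b_lab <- c(b_lab, at$label[j]); len <- c(len, dmin)
      }
    }
  }
  bonds <- tibble::tibble(a = a_lab, b = b_lab, length = len)
  adjacency <- stats::setNames(lapply(at$label, function(lb) {
    sort(c(bonds$b[bonds$a == lb], bonds$a[bonds$b == lb]))
  }), at$label)
  g <- list(bonds = bonds, adjacency = adjacency,
            ring_atoms = find_ring_atoms(adjacency, max_size = 7L))
  class(g) <- "bond_graph"
  g
}

#' @export
print.bond_graph <- function(x, ...) {
  cat(sprintf("<bond_graph> %d bond(s), %d atom(s), %d ring atom(s)\n",
              nrow(x$bonds), length(x$adjacency), length(x$ring_atoms)))
  invisible(x)
}

# labels of atoms lying on a cycle of size <= max_size
find_ring_atoms <- function(adjacency, max_size = 7L) {
  labs <- names(adjacency)
  in_ring <- character(0)
  for (start in labs) {
    if (start %in% in_ring) next
    # depth-limited DFS looking for a cycle through `start`
    found <- FALSE
    stack <- list(list(node = start, path = start))
    while (length(stack) && !found) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (length(cur$path) > max_size) next
      for (nb in adjacency[[cur$node]]) {
        if (nb == start && length(cur$path) >= 3) { found <- TRUE; break }
        if (!(nb %in% cur$path)) {
          stack[[length(stack) + 1L]] <- list(node = nb, path = c(cur$path, nb))
        }
      }
    }
    if (found) in_ring <- c(in_ring, start)
  }
  in_ring
}

# Neighbours used for typing: an ordered atom bonded to several alternative
# conformers counts each disorder pair once (only the lowest part id among
# its part>0 neighbours is kept), so both conformations see one substituent.
effective_neighbors <- function(graph, structure, lb) {
  part <- stats::setNames(structure$atoms$part, structure$atoms$label)
  nbs <- graph$adjacency[[lb]]
  if (!length(nbs)) return(nbs)
  p_nb <- part[nbs]
  if (all(p_nb == 0)) return(nbs)
  keep_part <- min(p_nb[p_nb > 0])
  nbs[p_nb == 0 | p_nb == keep_part | p_nb == part[lb]]
}

# degree counting only non-hydrogen effective neighbours, for typing signatures
heavy_degree <- function(graph, structure) {
  el <- stats::setNames(structure$atoms$element, structure$atoms$label)
  vapply(names(graph$adjacency), function(lb) {
    sum(el[effective_neighbors(graph, structure, lb)] != "H")
  }, 0L)
}
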