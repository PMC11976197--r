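# Canonical serialization of molecular graphs.
#
# Used to deduplicate fragment ions reached by different routes.  Atom
# invariants (element, charge, radical count, hydrogen count, aromaticity)
# are refined by two Weisfeiler-Lehman rounds over (neighbour colour, bond
# order, bond aromaticity), then igraph's BLISS solver produces a canonical
# vertex order and the graph is serialized to a readable line.  Equal graphs
# (up to automorphism) give equal keys; charge and radical state are part of
# the key.

wl_colors <- function(g, rounds = 2) {
  inv <- paste(g$atoms$element, g$atoms$charge, g$atoms$nrad,
               g$atoms$hcount, g$atoms$aromatic)
  col <- match(inv, sort(unique(inv)))
  if (nrow(g$bonds) == 0 || rounds == 0) return(as.integer(col))
  nbr <- vector("list", n_atoms(g))
  for (k in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a1[k]; b <- g$bonds$a2[k]
    lab <- paste0(g$bonds$order[k], ifelse(g$bonds$aromatic[k], "a", ""))
    nbr[[a]] <- c(nbr[[a]], list(c(b, lab)))
    nbr[[b]] <- c(nbr[[b]], list(c(a, lab)))
  }
  for (r in seq_len(rounds)) {
    sig <- vapply(seq_len(n_atoms(g)), function(i) {
      ns <- vapply(nbr[[i]], function(x) paste0(col[as.integer(x[1])], ":", x[2]), "")
      paste(col[i], paste(sort(ns), collapse = "|"))
    }, "")
    col <- match(sig, sort(unique(sig)))
  }
  as.integer(col)
}

#' Canonical key of a molecular graph
#'
#' Deterministic serialization that is invariant under atom reordering.
#' Two graphs have the same key iff they are identical up to automorphism,
#' including formal charges, radical counts, implicit hydrogens and bond
#' orders.
#'
#' @param graph a `molgraph`.
#' @return A single string.
#' @export
canonical_key <- function(graph) {
  n <- n_atoms(graph)
  if (n == 0) return("<empty>")
  h <- graph_value_hash(graph)
  if (is.null(.cidfrag_env$key_cache)) {
    .cidfrag_env$key_cache <- new.env(parent = emptyenv())
  }
  hit <- .cidfrag_env$key_cache[[h]]
  if (!is.null(hit)) return(hit)
  col <- wl_colors(graph)
  perm <- if (n == 1) 1L else {
    ig <- as_igraph(graph)
    igraph::canonical_permutation(ig, colors = col)$labeling
  }
  # perm maps old index -> canonical position
  inv <- integer(n); inv[perm] <- seq_len(n)
  a <- graph$atoms[inv, , drop = FALSE]
  atom_str <- paste0(a$element,
                     ifelse(a$aromatic, "~", ""),
                     "H", a$hcount,
                     ifelse(a$charge != 0, sprintf("%+d", a$charge), ""),
                     ifelse(a$nrad > 0, paste0("r", a$nrad), ""))
  if (nrow(graph$bonds) > 0) {
    b1 <- pmin(perm[graph$bonds$a1], perm[graph$bonds$a2])
    b2 <- pmax(perm[graph$bonds$a1], perm[graph$bonds$a2])
    o <- order(b1, b2)
    bond_str <- paste0(b1[o], "-", b2[o], ":", graph$bonds$order[o],
                       ifelse(graph$bonds$aromatic[o], "a", ""))
  } else bond_str <- character(0)
  key <- paste0(paste(atom_str, collapse = ","), "|",
                paste(bond_str, collapse = ","))
  .cidfrag_env$key_cache[[h]] <- key
  key
}
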