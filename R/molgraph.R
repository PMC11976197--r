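# Attributed molecular graphs.
#
# Atoms carry: element, formal charge, unpaired-electron count, implicit
# hydrogen count, aromatic flag.  Bonds carry: endpoint indices, kekulized
# bond order (1/2/3) and an aromatic flag.  Explicit hydrogen atoms are never
# stored; all hydrogens live in `hcount`, which keeps rule edits (proton and
# hydride moves) O(1).

# ---- valence model -------------------------------------------------------

# allowed total valences (sum of bond orders + implicit H) per element,
# adjusted by formal charge.  NULL means "element/charge combination invalid".
allowed_valences <- function(element, charge = 0L) {
  base <- switch(element,
    H = 1L, C = 4L, N = 3L, O = 2L, S = c(2L, 4L, 6L), P = c(3L, 5L),
    F = 1L, Cl = 1L, Br = 1L, I = 1L, NULL)
  if (is.null(base)) return(NULL)
  if (charge == 0L) return(base)
  if (charge == 1L) {
    return(switch(element,
      C = 3L, N = 4L, O = 3L, S = c(3L, 5L), P = c(4L, 6L),
      F = 2L, Cl = 2L, Br = 2L, I = 2L, H = 0L, NULL))
  }
  if (charge == -1L) {
    return(switch(element,
      C = 3L, N = 2L, O = 1L, S = c(1L, 3L, 5L), P = c(2L, 4L), NULL))
  }
  NULL
}

#' Construct a molecular graph
#'
#' @param atoms data frame with columns `element`, `charge`, `nrad`
#'   (unpaired electrons), `hcount` (implicit hydrogens), `aromatic`.
#' @param bonds data frame with columns `a1`, `a2` (atom indices),
#'   `order` (1, 2 or 3; kekulized) and `aromatic`.
#' @param validate check valences and reperceive aromaticity?
#' @return An object of class `molgraph`.
#' @export
molgraph <- function(atoms, bonds = NULL, validate = TRUE) {
  if (is.null(bonds) || nrow(bonds) == 0) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0),
                        order = integer(0), aromatic = logical(0))
  }
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$nrad)) atoms$nrad <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
  g <- structure(list(atoms = atoms, bonds = bonds), class = "molgraph")
  if (validate) {
    g <- perceive_aromaticity(g)
    validate_molgraph(g)
  }
  g
}

n_atoms <- function(g) nrow(g$atoms)

#' Net charge of a molecular graph
#' @param g a `molgraph`.
#' @export
net_charge <- function(g) sum(g$atoms$charge)

#' Is the graph an open-shell (radical) species?
#' @param g a `molgraph`.
#' @export
is_radical <- function(g) (sum(g$atoms$nrad) %% 2L) == 1L

# sum of bond orders incident to each atom (kekulized)
bond_order_sums <- function(g) {
  s <- numeric(n_atoms(g))
  if (nrow(g$bonds) > 0) {
    for (k in seq_len(nrow(g$bonds))) {
      s[g$bonds$a1[k]] <- s[g$bonds$a1[k]] + g$bonds$order[k]
      s[g$bonds$a2[k]] <- s[g$bonds$a2[k]] + g$bonds$order[k]
    }
  }
  s
}

atom_degree <- function(g) {
  d <- integer(n_atoms(g))
  if (nrow(g$bonds) > 0) {
    t1 <- table(factor(g$bonds$a1, levels = seq_len(n_atoms(g))))
    t2 <- table(factor(g$bonds$a2, levels = seq_len(n_atoms(g))))
    d <- as.integer(t1 + t2)
  }
  d
}

#' Check valence validity of a molecular graph
#'
#' Every atom's total valence (bond orders + implicit H) must lie in the
#' allowed set for its element, formal charge and radical count.
#'
#' @param g a `molgraph`.
#' @param quiet return FALSE instead of raising an error?
#' @return TRUE (invisibly) if valid.
#' @export
validate_molgraph <- function(g, quiet = FALSE) {
  bs <- bond_order_sums(g)
  for (i in seq_len(n_atoms(g))) {
    av <- allowed_valences(g$atoms$element[i], g$atoms$charge[i])
    tot <- bs[i] + g$atoms$hcount[i] + g$atoms$nrad[i]
    ok <- !is.null(av) && tot %in% av
    if (!ok) {
      if (quiet) return(FALSE)
      abort(sprintf(
        "valence violation at atom %d (%s, charge %+d, radical %d): total valence %s",
        i, g$atoms$element[i], g$atoms$charge[i], g$atoms$nrad[i], tot),
        class = "cidfrag_valence_error")
    }
  }
  invisible(TRUE)
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = if (nrow(g$bonds) > 0) g$bonds[, c("a1", "a2")] else
      data.frame(a1 = integer(0), a2 = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(g))))
}

# ---- rings and aromaticity ----------------------------------------------

# exact-representation hash of a graph (aromatic flags excluded: they are a
# derived property); used as a memoization key for perception and
# canonicalization.  Different atom orders of the same molecule hash
# differently -- that is only a cache miss, never an incorrect hit.
graph_value_hash <- function(g) {
  rlang::hash(list(g$atoms$element, g$atoms$charge, g$atoms$nrad,
                   g$atoms$hcount, g$bonds$a1, g$bonds$a2, g$bonds$order))
}

# logical vector over bonds: is the bond in a ring?
ring_bond_flags <- function(g) {
  if (nrow(g$bonds) == 0) return(logical(0))
  ig <- as_igraph(g)
  br <- igraph::bridges(ig)
  flags <- rep(TRUE, nrow(g$bonds))
  if (length(br) > 0) flags[as.integer(br)] <- FALSE
  flags
}

# smallest rings (unique atom sets) of size <= max_size
find_rings <- function(g, max_size = 7) {
  if (nrow(g$bonds) == 0) return(list())
  ig <- as_igraph(g)
  ringb <- which(ring_bond_flags(g))
  rings <- list()
  seen <- character(0)
  for (k in ringb) {
    a <- g$bonds$a1[k]; b <- g$bonds$a2[k]
    ig2 <- igraph::delete_edges(ig, igraph::get_edge_ids(ig, c(a, b)))
    sp <- suppressWarnings(igraph::shortest_paths(ig2, from = a, to = b)$vpath[[1]])
    if (length(sp) == 0) next
    ring <- as.integer(igraph::as_ids(sp))
    if (length(ring) > max_size) next
    key <- paste(sort(ring), collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1]] <- ring  # ordered cycle (a ... b)
    }
  }
  rings
}

# Aromaticity perception on the kekulized graph.  A 5- or 6-ring is aromatic
# if every ring atom contributes to the pi system (1 electron from an
# in-ring double bond; 2 from a lone pair on N/O/S with no double bond) and
# the electron count is 6.  A second pass accepts fused systems where an
# atom's double-bond partner is already aromatic (naphthalene-type kekule
# structures).  This model is intentionally simple and frozen by tests.
perceive_aromaticity <- function(g) {
  h <- graph_value_hash(g)
  if (is.null(.cidfrag_env$arom_cache)) {
    .cidfrag_env$arom_cache <- new.env(parent = emptyenv())
  }
  hit <- .cidfrag_env$arom_cache[[h]]
  if (!is.null(hit)) {
    g$atoms$aromatic <- hit$atoms
    g$bonds$aromatic <- hit$bonds
    return(g)
  }
  g <- perceive_aromaticity_impl(g)
  .cidfrag_env$arom_cache[[h]] <- list(atoms = g$atoms$aromatic,
                                       bonds = g$bonds$aromatic)
  g
}

perceive_aromaticity_impl <- function(g) {
  g$atoms$aromatic <- FALSE
  g$bonds$aromatic <- rep(FALSE, nrow(g$bonds))
  rings <- find_rings(g, max_size = 6)
  rings <- rings[vapply(rings, length, 1L) %in% c(5L, 6L)]
  if (length(rings) == 0) return(g)
  # per-atom double bond partners
  dbl <- vector("list", n_atoms(g))
  if (nrow(g$bonds) > 0) {
    for (k in seq_len(nrow(g$bonds))) {
      if (g$bonds$order[k] == 2) {
        dbl[[g$bonds$a1[k]]] <- c(dbl[[g$bonds$a1[k]]], g$bonds$a2[k])
        dbl[[g$bonds$a2[k]]] <- c(dbl[[g$bonds$a2[k]]], g$bonds$a1[k])
      }
    }
  }
  ring_pi <- function(ring, allow_aromatic_partner) {
    total <- 0L
    for (a in ring) {
      partners <- dbl[[a]]
      el <- g$atoms$element[a]
      if (length(partners) > 0) {
        if (any(partners %in% ring)) total <- total + 1L
        else if (allow_aromatic_partner && any(g$atoms$aromatic[partners]))
          total <- total + 1L
        else return(NA_integer_)   # exocyclic double bond: not aromatic
      } else if (el %in% c("N", "O", "S")) {
        total <- total + 2L        # lone pair enters the ring
      } else {
        return(NA_integer_)        # sp3 carbon
      }
    }
    total
  }
  for (pass in 1:2) {
    for (ring in rings) {
      pi_e <- ring_pi(ring, allow_aromatic_partner = (pass == 2))
      if (!is.na(pi_e) && pi_e == 6L) {
        g$atoms$aromatic[ring] <- TRUE
        for (i in seq_along(ring)) {
          a <- ring[i]; b <- ring[if (i == length(ring)) 1 else i + 1]
          hit <- (g$bonds$a1 == a & g$bonds$a2 == b) |
                 (g$bonds$a1 == b & g$bonds$a2 == a)
          g$bonds$aromatic[hit] <- TRUE
        }
      }
    }
  }
  g
}

# ---- SMILES input --------------------------------------------------------

# light syntax validation: OpenBabel silently repairs malformed SMILES, so
# structural errors are caught here with a pointer to the offending token.
check_smiles_syntax <- function(smiles) {
  if (!nzchar(trimws(smiles))) {
    abort("empty SMILES string", class = "cidfrag_parse_error")
  }
  chars <- strsplit(smiles, "")[[1]]
  depth <- 0; in_bracket <- FALSE
  ring <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_bracket) {
      if (ch == "]") in_bracket <- FALSE
      next
    }
    if (ch == "[") { in_bracket <- TRUE; next }
    if (ch == "(") depth <- depth + 1
    if (ch == ")") {
      depth <- depth - 1
      if (depth < 0) {
        abort(sprintf("SMILES parse error at position %d: unmatched ')'", i),
              class = "cidfrag_parse_error")
      }
    }
    if (grepl("[0-9]", ch)) {
      d <- as.integer(ch)
      ring <- if (d %in% ring) setdiff(ring, d) else c(ring, d)
    }
    if (!grepl("[A-Za-z0-9()=#+@.:~/\\\\-]", ch, perl = TRUE)) {
      abort(sprintf("SMILES parse error at position %d: unexpected token '%s'",
                    i, ch), class = "cidfrag_parse_error")
    }
  }
  if (in_bracket) abort("SMILES parse error: unterminated '['",
                        class = "cidfrag_parse_error")
  if (depth != 0) abort("SMILES parse error: unmatched '('",
                        class = "cidfrag_parse_error")
  if (length(ring) > 0) {
    abort(paste0("SMILES parse error: unclosed ring bond(s) ",
                 paste(ring, collapse = ", ")), class = "cidfrag_parse_error")
  }
  invisible(TRUE)
}

# old-style ctab charge codes
.ctab_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                  `5` = -1L, `6` = -2L, `7` = -3L)

# minimal V2000 molblock reader (ChemmineR's SDF reader rejects single-atom
# molecules such as water, so the OpenBabel molblock is read directly)
parse_molblock <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na)) abort("malformed molblock", class = "cidfrag_parse_error")
  atoms <- data.frame(element = character(na), charge = integer(na),
                      nrad = integer(na), hcount = integer(na),
                      aromatic = logical(na))
  for (i in seq_len(na)) {
    ln <- lines[4 + i]
    atoms$element[i] <- trimws(substr(ln, 32, 34))
    code <- suppressWarnings(as.integer(trimws(substr(ln, 37, 39))))
    atoms$charge[i] <- .ctab_charge[as.character(code %||% 0L)]
  }
  bonds <- data.frame(a1 = integer(nb), a2 = integer(nb),
                      order = integer(nb), aromatic = logical(nb))
  for (k in seq_len(nb)) {
    ln <- lines[4 + na + k]
    bonds$a1[k] <- as.integer(substr(ln, 1, 3))
    bonds$a2[k] <- as.integer(substr(ln, 4, 6))
    bonds$order[k] <- as.integer(substr(ln, 7, 9))
  }
  # property block: M CHG overrides atom-line codes, M RAD sets radicals
  prop <- grep("^M  (CHG|RAD)", lines, value = TRUE)
  if (any(grepl("^M  CHG", prop))) atoms$charge[] <- 0L
  for (ln in prop) {
    kind <- substr(ln, 4, 6)
    n <- as.integer(substr(ln, 7, 9))
    for (j in seq_len(n)) {
      at <- as.integer(substr(ln, 10 + (j - 1) * 8, 13 + (j - 1) * 8))
      val <- as.integer(substr(ln, 14 + (j - 1) * 8, 17 + (j - 1) * 8))
      if (kind == "CHG") atoms$charge[at] <- val
      if (kind == "RAD") atoms$nrad[at] <- if (val == 2L) 1L else 0L
    }
  }
  list(atoms = atoms, bonds = bonds)
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a
}

#' Parse a SMILES string into a molecular graph
#'
#' SMILES interpretation (including kekulization of aromatic input) is done
#' by OpenBabel via \pkg{ChemmineOB}; implicit hydrogen counts are assigned
#' from the package valence model and aromaticity is perceived on the
#' kekulized graph.
#'
#' @param smiles a SMILES string.
#' @return A `molgraph`.
#' @export
parse_structure <- function(smiles) {
  check_smiles_syntax(smiles)
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", source = smiles),
    error = function(e) abort(paste0("SMILES parse error: ", conditionMessage(e)),
                              class = "cidfrag_parse_error"))
  mb <- parse_molblock(txt)
  if (nrow(mb$atoms) == 0) {
    abort(paste0("SMILES parse error: no atoms parsed from '", smiles, "'"),
          class = "cidfrag_parse_error")
  }
  # fold any explicit hydrogens into neighbour hcount
  g <- molgraph(mb$atoms, mb$bonds, validate = FALSE)
  hyd <- which(g$atoms$element == "H")
  if (length(hyd) > 0) {
    for (h in hyd) {
      nb <- c(g$bonds$a2[g$bonds$a1 == h], g$bonds$a1[g$bonds$a2 == h])
      if (length(nb) == 1) g$atoms$hcount[nb] <- g$atoms$hcount[nb] + 1L
    }
    keep <- setdiff(seq_len(n_atoms(g)), hyd)
    g <- induced_molgraph(g, keep, validate = FALSE)
  }
  g <- assign_implicit_h(g)
  g <- perceive_aromaticity(g)
  validate_molgraph(g)
  g
}

# fill hcount to the smallest allowed valence
assign_implicit_h <- function(g) {
  bs <- bond_order_sums(g)
  for (i in seq_len(n_atoms(g))) {
    av <- allowed_valences(g$atoms$element[i], g$atoms$charge[i])
    if (is.null(av)) {
      abort(sprintf("unsupported element/charge at atom %d: %s%+d",
                    i, g$atoms$element[i], g$atoms$charge[i]),
            class = "cidfrag_valence_error")
    }
    need <- bs[i] + g$atoms$hcount[i] + g$atoms$nrad[i]
    fit <- av[av >= need]
    if (length(fit) == 0) {
      abort(sprintf("valence violation at atom %d (%s): %d bonds exceed allowed %s",
                    i, g$atoms$element[i], need, paste(av, collapse = "/")),
            class = "cidfrag_valence_error")
    }
    g$atoms$hcount[i] <- g$atoms$hcount[i] + as.integer(min(fit) - need)
  }
  g
}

# subgraph on a set of atoms (bonds within the set), reindexed
induced_molgraph <- function(g, atoms_keep, validate = TRUE) {
  idx <- stats::setNames(seq_along(atoms_keep), atoms_keep)
  keep_b <- g$bonds$a1 %in% atoms_keep & g$bonds$a2 %in% atoms_keep
  b <- g$bonds[keep_b, , drop = FALSE]
  if (nrow(b) > 0) {
    b$a1 <- as.integer(idx[as.character(b$a1)])
    b$a2 <- as.integer(idx[as.character(b$a2)])
  }
  molgraph(g$atoms[atoms_keep, , drop = FALSE], b, validate = validate)
}

#' Split a molecular graph into connected components
#' @param g a `molgraph`.
#' @return A list of `molgraph`s (each reperceived for aromaticity).
#' @export
graph_components <- function(g) {
  if (n_atoms(g) == 0) return(list())
  comp <- igraph::components(as_igraph(g))$membership
  lapply(seq_len(max(comp)), function(ci) {
    induced_molgraph(g, which(comp == ci), validate = FALSE) |>
      perceive_aromaticity()
  })
}

#' Elemental formula of a molecular graph
#'
#' Counts include implicit hydrogens; charge and radical state are copied
#' from the graph.
#'
#' @param graph a `molgraph`.
#' @return An `elemental_formula`.
#' @export
formula_of <- function(graph) {
  counts <- table(graph$atoms$element)
  counts <- stats::setNames(as.integer(counts), names(counts))
  h <- sum(graph$atoms$hcount)
  if (h > 0) counts["H"] <- (counts["H"] %||% 0L) + as.integer(h)
  elemental_formula(counts, charge = net_charge(graph),
                    radical = is_radical(graph))
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %s: %d atoms, %d bonds, charge %+d%s\n",
              format(formula_of(x)), n_atoms(x), nrow(x$bonds),
              net_charge(x), if (is_radical(x)) ", radical" else ""))
  invisible(x)
}

# V2000 molblock writer (external evaluator decks, debugging)
write_molblock <- function(g, title = "cidfrag") {
  na <- n_atoms(g); nb <- nrow(g$bonds)
  lines <- c(title, "  cidfrag", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  for (i in seq_len(na)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              0, 0, 0, g$atoms$element[i]))
  }
  for (k in seq_len(nb)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              g$bonds$a1[k], g$bonds$a2[k], g$bonds$order[k]))
  }
  chg <- which(g$atoms$charge != 0)
  if (length(chg) > 0) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, g$atoms$charge[chg]),
                                    collapse = "")))
  }
  rad <- which(g$atoms$nrad > 0)
  if (length(rad) > 0) {
    lines <- c(lines, paste0("M  RAD", sprintf("%3d", length(rad)),
                             paste0(sprintf("%4d%4d", rad, 2L), collapse = "")))
  }
  paste(c(lines, "M  END", "$$$$", ""), collapse = "\n")
}
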