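# SMARTS-subset trigger patterns.
#
# The rule registry drives graph edits from atom mappings, which no installed
# toolkit exposes, so matching is done in-package: a pattern is parsed into a
# small graph of atom/bond constraint sets and embeddings are enumerated with
# igraph's LAD monomorphism solver, using per-atom candidate domains for the
# atom constraints and a post-filter for the bond constraints.
#
# Supported atom syntax: organic-subset symbols (C N O S P F Cl Br I, lower
# case = aromatic), '*', and bracket atoms [<elem>(,<elem>...)<primitives>]
# with primitives Hn (exact total hydrogen count), Xn (connectivity incl. H),
# + / +n / - / -n (formal charge; unspecified = any).  Supported bond syntax:
# default (single-or-aromatic), '-' single, '=' double, '#' triple, ':'
# aromatic, '~' any, with optional ring qualifiers '@' / '!@'.  '.' separates
# disconnected components (matched with disjoint atom sets).  Ring-closure
# digits and branches follow SMILES.  Bond orders refer to the kekulized
# graph; ':' and the default bond also accept any aromatic-flagged bond.

smarts_bond_spec <- function(sym = "") {
  spec <- list(order = NA_integer_, aromatic = NA, ring = NA, default = FALSE)
  ring <- NA
  if (grepl("!@", sym, fixed = TRUE)) { ring <- FALSE; sym <- sub("!@", "", sym, fixed = TRUE) }
  else if (grepl("@", sym, fixed = TRUE)) { ring <- TRUE; sym <- sub("@", "", sym, fixed = TRUE) }
  spec$ring <- ring
  if (sym == "") { spec$default <- TRUE; return(spec) }
  if (sym == "-") { spec$order <- 1L; spec$aromatic <- FALSE }
  else if (sym == "=") { spec$order <- 2L; spec$aromatic <- FALSE }
  else if (sym == "#") { spec$order <- 3L }
  else if (sym == ":") { spec$aromatic <- TRUE }
  else if (sym == "~") { }
  else abort(paste0("invalid SMARTS bond symbol: ", sym),
             class = "cidfrag_smarts_error")
  spec
}

parse_bracket_atom <- function(body, pos) {
  spec <- list(elems = character(0), arom = logical(0),
               hcount = NA_integer_, conn = NA_integer_, charge = NA_integer_)
  # leading element alternatives separated by commas
  rest <- body
  repeat {
    m <- regmatches(rest, regexpr("^(Cl|Br|[CNOSPFI]|[cnosp]|\\*|#[0-9]+)", rest))
    if (length(m) == 0) break
    tok <- m
    rest <- substr(rest, nchar(tok) + 1, nchar(rest))
    if (grepl("^#", tok)) {
      num <- as.integer(substr(tok, 2, nchar(tok)))
      sym <- c(`6` = "C", `7` = "N", `8` = "O", `16` = "S", `15` = "P")[as.character(num)]
      if (is.na(sym)) abort(paste0("unsupported atomic number in SMARTS: ", tok),
                            class = "cidfrag_smarts_error")
      spec$elems <- c(spec$elems, unname(sym)); spec$arom <- c(spec$arom, NA)
    } else if (tok == "*") {
      spec$elems <- c(spec$elems, "*"); spec$arom <- c(spec$arom, NA)
    } else {
      lower <- tok %in% c("c", "n", "o", "s", "p")
      spec$elems <- c(spec$elems, toupper(tok))
      spec$arom <- c(spec$arom, lower)
    }
    if (grepl("^,", rest)) { rest <- substr(rest, 2, nchar(rest)); next }
    break
  }
  # primitives
  while (nzchar(rest)) {
    if (grepl("^H[0-9]?", rest)) {
      m <- regmatches(rest, regexpr("^H[0-9]?", rest))
      spec$hcount <- if (nchar(m) == 1) 1L else as.integer(substr(m, 2, 2))
      rest <- substr(rest, nchar(m) + 1, nchar(rest))
    } else if (grepl("^X[0-9]", rest)) {
      spec$conn <- as.integer(substr(rest, 2, 2))
      rest <- substr(rest, 3, nchar(rest))
    } else if (grepl("^\\+[0-9]?", rest)) {
      m <- regmatches(rest, regexpr("^\\+[0-9]?", rest))
      spec$charge <- if (nchar(m) == 1) 1L else as.integer(substr(m, 2, 2))
      rest <- substr(rest, nchar(m) + 1, nchar(rest))
    } else if (grepl("^-[0-9]?", rest)) {
      m <- regmatches(rest, regexpr("^-[0-9]?", rest))
      spec$charge <- if (nchar(m) == 1) -1L else -as.integer(substr(m, 2, 2))
      rest <- substr(rest, nchar(m) + 1, nchar(rest))
    } else {
      abort(sprintf("invalid SMARTS primitive at position %d: '%s'", pos, rest),
            class = "cidfrag_smarts_error")
    }
  }
  if (length(spec$elems) == 0) {
    abort(sprintf("SMARTS bracket atom without element at position %d", pos),
          class = "cidfrag_smarts_error")
  }
  spec
}

#' Parse a SMARTS-subset pattern
#'
#' @param pattern pattern string (see package vignette for the dialect).
#' @return An object of class `smarts_pattern` with atoms, bonds and
#'   component assignment.
#' @export
parse_smarts <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  atoms <- list(); bonds <- list()
  comp <- integer(0)
  cur_comp <- 1L
  prev <- NA_integer_
  stack <- integer(0)
  pending_bond <- ""
  ring_open <- list()
  i <- 1
  add_atom <- function(spec) {
    atoms[[length(atoms) + 1]] <<- spec
    comp[length(atoms)] <<- cur_comp
    idx <- length(atoms)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1]] <<- list(a = prev, b = idx,
                                          spec = smarts_bond_spec(pending_bond))
    }
    pending_bond <<- ""
    prev <<- idx
  }
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= length(chars) && chars[j] != "]") j <- j + 1
      if (j > length(chars)) abort("unterminated '[' in SMARTS",
                                   class = "cidfrag_smarts_error")
      add_atom(parse_bracket_atom(paste(chars[(i + 1):(j - 1)], collapse = ""), i))
      i <- j + 1
    } else if (grepl("^(Cl|Br)", paste(chars[i:min(i + 1, length(chars))], collapse = ""))) {
      sym <- paste(chars[i:(i + 1)], collapse = "")
      add_atom(list(elems = sym, arom = FALSE, hcount = NA_integer_,
                    conn = NA_integer_, charge = NA_integer_))
      i <- i + 2
    } else if (ch %in% c("C", "N", "O", "S", "P", "F", "I")) {
      add_atom(list(elems = ch, arom = FALSE, hcount = NA_integer_,
                    conn = NA_integer_, charge = NA_integer_))
      i <- i + 1
    } else if (ch %in% c("c", "n", "o", "s", "p")) {
      add_atom(list(elems = toupper(ch), arom = TRUE, hcount = NA_integer_,
                    conn = NA_integer_, charge = NA_integer_))
      i <- i + 1
    } else if (ch == "*") {
      add_atom(list(elems = "*", arom = NA, hcount = NA_integer_,
                    conn = NA_integer_, charge = NA_integer_))
      i <- i + 1
    } else if (ch %in% c("-", "=", "#", ":", "~", "@", "!")) {
      sym <- ch
      while (i + 1 <= length(chars) && chars[i + 1] %in% c("@", "-", "=", "#", ":", "~")) {
        i <- i + 1; sym <- paste0(sym, chars[i])
      }
      pending_bond <- sym
      i <- i + 1
    } else if (grepl("[0-9]", ch)) {
      d <- ch
      if (!is.null(ring_open[[d]])) {
        op <- ring_open[[d]]
        bsym <- if (nzchar(pending_bond)) pending_bond else op$bond
        bonds[[length(bonds) + 1]] <- list(a = op$atom, b = prev,
                                           spec = smarts_bond_spec(bsym))
        ring_open[[d]] <- NULL
      } else {
        ring_open[[d]] <- list(atom = prev, bond = pending_bond)
      }
      pending_bond <- ""
      i <- i + 1
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1
    } else if (ch == ")") {
      if (length(stack) == 0) abort("unmatched ')' in SMARTS",
                                    class = "cidfrag_smarts_error")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1
    } else if (ch == ".") {
      cur_comp <- cur_comp + 1L
      prev <- NA_integer_
      i <- i + 1
    } else {
      abort(sprintf("invalid SMARTS token '%s' at position %d", ch, i),
            class = "cidfrag_smarts_error")
    }
  }
  if (length(Filter(Negate(is.null), ring_open)) > 0) {
    abort("unclosed ring bond in SMARTS", class = "cidfrag_smarts_error")
  }
  structure(list(atoms = atoms, bonds = bonds, comp = comp, pattern = pattern),
            class = "smarts_pattern")
}

atom_spec_matches <- function(spec, g, degrees) {
  n <- n_atoms(g)
  ok <- rep(FALSE, n)
  for (j in seq_along(spec$elems)) {
    el <- spec$elems[j]
    hit <- if (el == "*") rep(TRUE, n) else g$atoms$element == el
    if (!is.na(spec$arom[j])) hit <- hit & (g$atoms$aromatic == spec$arom[j])
    ok <- ok | hit
  }
  if (!is.na(spec$hcount)) ok <- ok & (g$atoms$hcount == spec$hcount)
  if (!is.na(spec$conn)) ok <- ok & ((degrees + g$atoms$hcount) == spec$conn)
  if (!is.na(spec$charge)) ok <- ok & (g$atoms$charge == spec$charge)
  which(ok)
}

bond_spec_ok <- function(spec, order, aromatic, in_ring) {
  if (!is.na(spec$ring) && spec$ring != in_ring) return(FALSE)
  if (spec$default) return(aromatic || order == 1L)
  if (!is.na(spec$order) && order != spec$order) return(FALSE)
  if (!is.na(spec$aromatic) && aromatic != spec$aromatic) return(FALSE)
  TRUE
}

# precomputed per-graph matching context
make_match_ctx <- function(g) {
  list(degrees = atom_degree(g), ringb = ring_bond_flags(g),
       tg = as_igraph(g),
       bond_key = paste(pmin(g$bonds$a1, g$bonds$a2),
                        pmax(g$bonds$a1, g$bonds$a2)))
}

# match one connected pattern component; returns list of integer maps
match_component <- function(pat, atom_idx, g, ctx) {
  doms <- lapply(pat$atoms[atom_idx], atom_spec_matches, g = g,
                 degrees = ctx$degrees)
  if (any(vapply(doms, length, 1L) == 0)) return(list())
  local_id <- stats::setNames(seq_along(atom_idx), atom_idx)
  pb <- Filter(function(b) b$a %in% atom_idx, pat$bonds)
  if (length(atom_idx) == 1) {
    return(lapply(doms[[1]], function(v) stats::setNames(v, atom_idx)))
  }
  pg <- igraph::make_graph(
    edges = unlist(lapply(pb, function(b) c(local_id[[as.character(b$a)]],
                                            local_id[[as.character(b$b)]]))),
    n = length(atom_idx), directed = FALSE)
  maps <- tryCatch(
    igraph::subgraph_isomorphisms(pattern = pg, target = ctx$tg, method = "lad",
                                  induced = FALSE, domains = lapply(doms, as.numeric)),
    error = function(e) list())
  if (length(maps) == 0) return(list())
  ringb <- ctx$ringb
  bond_key <- ctx$bond_key
  res <- list()
  for (m in maps) {
    mv <- as.integer(m)
    ok <- TRUE
    for (b in pb) {
      u <- mv[local_id[[as.character(b$a)]]]
      v <- mv[local_id[[as.character(b$b)]]]
      k <- match(paste(min(u, v), max(u, v)), bond_key)
      if (is.na(k) ||
          !bond_spec_ok(b$spec, g$bonds$order[k], g$bonds$aromatic[k], ringb[k])) {
        ok <- FALSE; break
      }
    }
    if (ok) res[[length(res) + 1]] <- stats::setNames(mv, atom_idx)
  }
  res
}

#' Find all embeddings of a SMARTS-subset pattern in a molecular graph
#'
#' @param graph a `molgraph`.
#' @param pattern pattern string or a parsed `smarts_pattern`.
#' @param ctx optional precomputed matching context (internal use).
#' @return A list of named integer vectors (pattern atom position ->
#'   graph atom index), in deterministic order (sorted by mapped tuple).
#'   Duplicate mappings are removed; automorphic images count as distinct
#'   embeddings, as in standard SMARTS semantics.
#' @export
match_pattern <- function(graph, pattern, ctx = NULL) {
  if (inherits(pattern, "smarts_pattern")) {
    pat <- pattern
  } else {
    if (is.null(.cidfrag_env$smarts_cache)) {
      .cidfrag_env$smarts_cache <- new.env(parent = emptyenv())
    }
    pat <- .cidfrag_env$smarts_cache[[pattern]]
    if (is.null(pat)) {
      pat <- parse_smarts(pattern)
      .cidfrag_env$smarts_cache[[pattern]] <- pat
    }
  }
  if (is.null(ctx)) ctx <- make_match_ctx(graph)
  comp_maps <- lapply(sort(unique(pat$comp)), function(ci) {
    match_component(pat, which(pat$comp == ci), graph, ctx)
  })
  if (any(vapply(comp_maps, length, 1L) == 0)) return(list())
  # combine disconnected components with disjoint atom sets
  combined <- comp_maps[[1]]
  for (cm in comp_maps[-1]) {
    combined <- unlist(lapply(combined, function(m1) {
      Filter(Negate(is.null), lapply(cm, function(m2) {
        if (length(intersect(m1, m2)) > 0) NULL else c(m1, m2)
      }))
    }), recursive = FALSE)
    if (length(combined) == 0) return(list())
  }
  # order by pattern position, dedupe, sort deterministically
  combined <- lapply(combined, function(m) {
    m[order(as.integer(names(m)))]
  })
  keys <- vapply(combined, function(m) paste(m, collapse = ","), "")
  combined <- combined[!duplicated(keys)]
  combined[order(vapply(combined, function(m) paste(sprintf("%06d", m), collapse = ","), ""))]
}
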