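# The fragmentation engine: ionization, stability-guided selection,
# stage-wise expansion by rules and weak-bond cleavage, tree construction.
#
# Depth counts mass-losing cleavage stages.  Within a stage the engine takes
# the closure over mass-preserving steps (rearrangement rules and ring
# heterolyses), bounded by a per-path per-rule application cap; cleavage
# products seed the next stage.  All iteration orders are canonical-key
# sorted, so trees are deterministic for a fixed configuration.

#' Engine configuration
#'
#' @param max_depth fragmentation depth in levels: level 0 is the protomer
#'   set, and `max_depth - 1` cleavage (mass-losing) stages follow, so
#'   `max_depth = 1` returns a root-only tree.  Mass-preserving
#'   rearrangements iterate within a stage under `rearrangement_cap`.
#' @param enthalpy_window kcal/mol above the reference minimum within which
#'   candidate ions are kept.
#' @param window_scope "parent" (default): the window is applied relative to
#'   the per-precursor minimum, so each precursor's most facile channels
#'   survive; "level": relative to the global per-level minimum.
#' @param max_ions_per_level truncation cap per level, ordered by
#'   (enthalpy, canonical key).
#' @param max_isomers_per_formula at each cleavage selection, at most this
#'   many structural isomers of one ion composition are retained (most
#'   stable first); keeps the level budget available for composition
#'   diversity, which is what peak annotation sees.
#' @param rearrangement_cap maximum applications of any one rearrangement
#'   rule along a root-to-leaf path.
#' @param max_rearrangement_rounds closure iterations per stage.
#' @param weak_bond_threshold bond-order threshold for weak-bond cleavage.
#' @param min_mz lower m/z bound for retained fragment ions (mirrors the
#'   instrument's lower scan limit; ions below it are never expanded).
#' @param backend stability backend id ("heuristic" or "external").
#' @param seed seed for any stochastic step (3D embedding of the external
#'   backend; the heuristic engine is fully deterministic).
#' @export
engine_config <- function(max_depth = 4L, enthalpy_window = 30,
                          window_scope = c("parent", "level"),
                          max_ions_per_level = 50L,
                          max_isomers_per_formula = 12L,
                          rearrangement_cap = 2L,
                          max_rearrangement_rounds = 6L,
                          weak_bond_threshold = 0.9, min_mz = 50,
                          backend = "heuristic", seed = 1L) {
  stopifnot(max_depth >= 1, enthalpy_window >= 0)
  structure(list(max_depth = as.integer(max_depth),
                 enthalpy_window = enthalpy_window,
                 window_scope = match.arg(window_scope),
                 max_ions_per_level = as.integer(max_ions_per_level),
                 max_isomers_per_formula = as.integer(max_isomers_per_formula),
                 rearrangement_cap = as.integer(rearrangement_cap),
                 max_rearrangement_rounds = as.integer(max_rearrangement_rounds),
                 weak_bond_threshold = weak_bond_threshold,
                 min_mz = min_mz,
                 backend = backend, seed = as.integer(seed),
                 ionization = "positive_protonation"),
            class = "engine_config")
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Protonate a neutral molecule at every basic site
#'
#' Positive-mode electrospray ionization model: one protomer per heteroatom
#' (N, O, S) lone pair able to accept a proton within its allowed valence;
#' pi-system (carbon) protonation is excluded.  All protomers share the
#' \[M+H\]+ formula and m/z; symmetric sites are merged by canonical key.
#'
#' @param graph neutral `molgraph`.
#' @return List of `ion_species` (empty, with a warning, if the molecule has
#'   no protonation site).
#' @export
ionize <- function(graph) {
  if (net_charge(graph) != 0) {
    abort("ionize() expects a neutral molecule", class = "cidfrag_ion_error")
  }
  bs <- bond_order_sums(graph)
  out <- list()
  seen <- character(0)
  for (i in seq_len(n_atoms(graph))) {
    el <- graph$atoms$element[i]
    if (!el %in% c("N", "O", "S")) next
    if (graph$atoms$charge[i] != 0) next
    av <- allowed_valences(el, 1L)
    tot <- bs[i] + graph$atoms$hcount[i] + graph$atoms$nrad[i] + 1L
    if (is.null(av) || !tot %in% av) next
    g <- graph
    g$atoms$hcount[i] <- g$atoms$hcount[i] + 1L
    g$atoms$charge[i] <- 1L
    g <- perceive_aromaticity(g)
    if (!validate_molgraph(g, quiet = TRUE)) next
    ion <- ion_species(g, label = sprintf("[M+H]+ (site %d)", i))
    if (!ion$key %in% seen) {
      seen <- c(seen, ion$key)
      out[[length(out) + 1]] <- ion
    }
  }
  if (length(out) == 0) {
    warn("molecule has no protonation site; empty protomer set")
  }
  out
}

#' Select chemically plausible candidates by reaction enthalpy
#'
#' Keeps candidates whose enthalpy lies within the configured window of the
#' reference minimum (per precursor by default, per level with
#' `window_scope = "level"`), then truncates to the per-level cap ordered by
#' (enthalpy, canonical key) -- fully deterministic.
#'
#' @param candidates a data frame / tibble with columns `key`, `enthalpy`,
#'   `parent_key` (list-columns allowed for the rest).
#' @param config an [engine_config()].
#' @param guarantee_parents parent keys whose single most favorable candidate
#'   is kept even beyond the level cap.  The engine passes the full stage
#'   pool: every ion already selected as chemically meaningful contributes at
#'   least its most facile channel, while the cap prunes the redundant rest.
#' @param isomer_cap maximum retained isomers per ion composition (the
#'   engine's cleavage step passes `config$max_isomers_per_formula`); needs a
#'   `formula` column in `candidates`.
#' @return The selected subset, in selection order.
#' @export
select_stable <- function(candidates, config, guarantee_parents = character(0),
                          isomer_cap = Inf) {
  if (nrow(candidates) == 0) return(candidates)
  if (config$window_scope == "level") {
    keep <- candidates$enthalpy <= min(candidates$enthalpy) + config$enthalpy_window
  } else {
    keep <- rep(FALSE, nrow(candidates))
    for (pk in unique(candidates$parent_key)) {
      idx <- which(candidates$parent_key == pk)
      keep[idx] <- candidates$enthalpy[idx] <=
        min(candidates$enthalpy[idx]) + config$enthalpy_window
    }
  }
  sel <- candidates[keep, , drop = FALSE]
  # cap ordering: window excess over the reference minimum (so one
  # precursor's facile channels cannot crowd out another's only channel),
  # then absolute enthalpy, then canonical key
  if (config$window_scope == "level") {
    excess <- sel$enthalpy - min(candidates$enthalpy)
  } else {
    pmin_map <- tapply(candidates$enthalpy, candidates$parent_key, min)
    excess <- sel$enthalpy - pmin_map[sel$parent_key]
  }
  sel <- sel[order(excess, sel$enthalpy, sel$key), , drop = FALSE]
  sel <- sel[!duplicated(sel$key), , drop = FALSE]
  if (is.finite(isomer_cap) && !is.null(sel$formula) && nrow(sel) > 0) {
    rank_in_formula <- stats::ave(seq_len(nrow(sel)), sel$formula,
                                  FUN = seq_along)
    sel <- sel[rank_in_formula <= isomer_cap, , drop = FALSE]
  }
  keep <- seq_len(nrow(sel)) <= config$max_ions_per_level
  if (length(guarantee_parents) > 0 && nrow(sel) > 0) {
    keep <- keep | !duplicated(sel$parent_key) &
      sel$parent_key %in% guarantee_parents
  }
  sel[keep, , drop = FALSE]
}

# weak-bond heterolysis channel: both charge-retention directions, filtered
# by valence validity (no negative formal charges; exactly one +1 product)
weak_bond_applications <- function(ion, energy, config) {
  wb <- weak_bonds(ion$graph, energy, config$weak_bond_threshold)
  out <- list()
  seen <- character(0)
  for (k in wb) {
    ends <- c(ion$graph$bonds$a1[k], ion$graph$bonds$a2[k])
    for (d in 1:2) {
      a <- ends[d]; b <- ends[3 - d]    # electrons go to a, charge to b
      g <- ion$graph
      g$bonds <- g$bonds[-k, , drop = FALSE]
      g$atoms$charge[a] <- g$atoms$charge[a] - 1L
      g$atoms$charge[b] <- g$atoms$charge[b] + 1L
      if (any(g$atoms$charge < 0)) next
      parts <- graph_components(g)
      chg <- vapply(parts, net_charge, 0L)
      if (sum(chg == 1L) != 1 || any(!chg %in% c(0L, 1L))) next
      if (!all(vapply(parts, validate_molgraph, TRUE, quiet = TRUE))) next
      prod_ion <- ion_species(parts[[which(chg == 1L)]],
                              provenance = list(parent = ion$key,
                                                rule = "weak_bond_cleavage"))
      neutrals <- parts[chg == 0L]
      kk <- paste(prod_ion$key,
                  paste(sort(vapply(neutrals, canonical_key, "")), collapse = ";"))
      if (kk %in% seen) next
      seen <- c(seen, kk)
      out[[length(out) + 1]] <- structure(
        list(rule_id = "weak_bond_cleavage", mapping = ends,
             ion = prod_ion, neutrals = neutrals,
             delta_mz = ion$mz - prod_ion$mz,
             is_cleavage = length(neutrals) > 0),
        class = "rule_application")
    }
  }
  out
}

#' Expand an ion by all rules and weak-bond cleavages
#'
#' Union of (a) every application of every registry rule and (b) heterolytic
#' cleavage of every weak bond in both charge-retention directions, filtered
#' by valence validity; deduplicated by product canonical key.  Each
#' application is annotated with its reaction enthalpy under `evaluator`.
#'
#' @param ion an `ion_species`.
#' @param registry named list of `frag_rule`s (default [builtin_registry()]).
#' @param evaluator from [make_evaluator()].
#' @param config an [engine_config()].
#' @return List of `rule_application`s with an `enthalpy` field.
#' @export
expand <- function(ion, registry = builtin_registry(),
                   evaluator = make_evaluator(), config = engine_config()) {
  ctx <- make_match_ctx(ion$graph)
  apps <- list()
  for (rid in sort(names(registry))) {
    apps <- c(apps, apply_rule(ion, registry[[rid]], ctx = ctx))
  }
  energy <- evaluator(ion$graph)
  apps <- c(apps, weak_bond_applications(ion, energy, config))
  seen <- character(0)
  out <- list()
  for (a in apps) {
    kk <- paste(a$ion$key,
                paste(sort(vapply(a$neutrals, canonical_key, "")), collapse = ";"))
    if (kk %in% seen) next
    seen <- c(seen, kk)
    a$enthalpy <- reaction_enthalpy(ion, c(list(a$ion$graph), a$neutrals),
                                    evaluator)
    out[[length(out) + 1]] <- a
  }
  out
}

# internal: candidate tibble from applications
apps_to_candidates <- function(apps, parent_key) {
  if (length(apps) == 0) {
    return(tibble(key = character(0), formula = character(0),
                  enthalpy = numeric(0), parent_key = character(0),
                  app = list()))
  }
  tibble(key = vapply(apps, function(a) a$ion$key, ""),
         formula = vapply(apps, function(a) format(a$ion$formula), ""),
         enthalpy = vapply(apps, function(a) a$enthalpy, 0),
         parent_key = parent_key,
         app = apps)
}

#' Fragment a molecule into a fragmentation tree
#'
#' Runs the engine: protonation (level 0 roots), then for each cleavage
#' stage the rearrangement closure of the frontier followed by stability
#' selection of all cleavage products.  Terminates at `max_depth` stages or
#' when no new canonical keys appear; ions reached by several routes are
#' merged with multiple parent edges.
#'
#' @param graph neutral input `molgraph` (or SMILES string).
#' @param config an [engine_config()].
#' @param registry rule registry.
#' @param evaluator stability evaluator (defaults to the configured backend).
#' @return A `frag_tree`.
#' @export
fragment <- function(graph, config = engine_config(),
                     registry = builtin_registry(), evaluator = NULL) {
  if (is.character(graph)) graph <- parse_structure(graph)
  if (is.null(evaluator)) evaluator <- make_evaluator(config$backend)

  nodes <- new.env(parent = emptyenv())   # key -> record
  edges <- list()
  ids <- character(0)                      # insertion order of keys
  add_node <- function(ion, stage, hof, rule_counts) {
    if (!is.null(nodes[[ion$key]])) {
      rec <- nodes[[ion$key]]
      rec$rule_counts <- pmin(rec$rule_counts, rule_counts)
      nodes[[ion$key]] <- rec
      return(FALSE)
    }
    nodes[[ion$key]] <- list(ion = ion, stage = stage, hof = hof,
                             rule_counts = rule_counts)
    ids <<- c(ids, ion$key)
    TRUE
  }
  add_edge <- function(parent_key, app) {
    edges[[length(edges) + 1]] <<- list(
      parent = parent_key, child = app$ion$key, rule = app$rule_id,
      neutrals = paste(vapply(app$neutrals, function(n) format(formula_of(n)), ""),
                       collapse = "+"),
      delta_mz = app$delta_mz, enthalpy = app$enthalpy)
  }

  protomers <- ionize(graph)
  zero_counts <- stats::setNames(integer(length(registry)), names(registry))
  if (length(protomers) == 0) {
    return(new_frag_tree(nodes, ids, edges, roots = character(0),
                         config = config))
  }
  root_cand <- tibble(
    key = vapply(protomers, function(p) p$key, ""),
    enthalpy = vapply(protomers, function(p) evaluator(p$graph)$hof, 0),
    parent_key = "M",
    app = lapply(protomers, function(p) list(ion = p)))
  root_sel <- select_stable(root_cand, config)
  for (i in seq_len(nrow(root_sel))) {
    add_node(root_sel$app[[i]]$ion, stage = 0L,
             hof = root_sel$enthalpy[i], rule_counts = zero_counts)
  }
  frontier <- root_sel$key
  roots <- frontier

  rearr_ids <- names(registry)[vapply(registry, function(r)
    r$kind == "rearrangement", TRUE)]

  app_cache <- new.env(parent = emptyenv())
  get_apps <- function(key) {
    if (is.null(app_cache[[key]])) {
      app_cache[[key]] <- expand(nodes[[key]]$ion, registry, evaluator, config)
    }
    app_cache[[key]]
  }

  for (stage in seq_len(config$max_depth - 1L)) {
    # ---- rearrangement closure within the stage -------------------------
    pool <- frontier
    wave <- frontier
    for (round in seq_len(config$max_rearrangement_rounds)) {
      if (length(wave) == 0) break
      cands <- list()
      for (k in sort(wave)) {
        rec <- nodes[[k]]
        blocked <- rearr_ids[rec$rule_counts[rearr_ids] >= config$rearrangement_cap]
        apps <- get_apps(k)
        apps <- Filter(function(a) !a$is_cleavage &&
                         !a$rule_id %in% blocked &&
                         a$ion$mz >= config$min_mz &&
                         is.null(nodes[[a$ion$key]]), apps)
        cands[[length(cands) + 1]] <- apps_to_candidates(apps, k)
      }
      cands <- dplyr::bind_rows(cands)
      sel <- select_stable(cands, config)
      new_wave <- character(0)
      for (i in seq_len(nrow(sel))) {
        app <- sel$app[[i]]
        pk <- sel$parent_key[i]
        counts <- nodes[[pk]]$rule_counts
        if (app$rule_id %in% rearr_ids) {
          counts[app$rule_id] <- counts[app$rule_id] + 1L
        }
        if (add_node(app$ion, stage = stage - 1L,
                     hof = evaluator(app$ion$graph)$hof, rule_counts = counts)) {
          new_wave <- c(new_wave, app$ion$key)
        }
        add_edge(pk, app)
      }
      pool <- c(pool, new_wave)
      wave <- new_wave
    }
    # ---- cleavage step --------------------------------------------------
    cands <- list()
    for (k in sort(pool)) {
      apps <- Filter(function(a) a$is_cleavage && a$ion$mz >= config$min_mz,
                     get_apps(k))
      cands[[length(cands) + 1]] <- apps_to_candidates(apps, k)
    }
    cands <- dplyr::bind_rows(cands)
    sel <- select_stable(cands, config, guarantee_parents = pool,
                         isomer_cap = config$max_isomers_per_formula)
    frontier <- character(0)
    for (i in seq_len(nrow(sel))) {
      app <- sel$app[[i]]
      pk <- sel$parent_key[i]
      if (add_node(app$ion, stage = stage,
                   hof = evaluator(app$ion$graph)$hof,
                   rule_counts = nodes[[pk]]$rule_counts)) {
        frontier <- c(frontier, app$ion$key)
      }
      add_edge(pk, app)
    }
    if (length(frontier) == 0) break
  }
  new_frag_tree(nodes, ids, edges, roots, config)
}

new_frag_tree <- function(nodes, ids, edges, roots, config) {
  id_of <- stats::setNames(seq_along(ids), ids)
  recs <- lapply(ids, function(k) nodes[[k]])
  node_tbl <- tibble(
    id = seq_along(ids),
    key = ids,
    formula = vapply(recs, function(r) format(r$ion$formula), ""),
    mz = vapply(recs, function(r) r$ion$mz, 0),
    charge = vapply(recs, function(r) r$ion$formula$charge, 0L),
    radical = vapply(recs, function(r) r$ion$formula$radical, TRUE),
    hof = vapply(recs, function(r) r$hof, 0),
    stage = vapply(recs, function(r) r$stage, 0L))
  edge_tbl <- if (length(edges) == 0) {
    tibble(parent = integer(0), child = integer(0), rule = character(0),
           neutrals = character(0), delta_mz = numeric(0), enthalpy = numeric(0))
  } else {
    tibble(
      parent = as.integer(id_of[vapply(edges, function(e) e$parent, "")]),
      child = as.integer(id_of[vapply(edges, function(e) e$child, "")]),
      rule = vapply(edges, function(e) e$rule, ""),
      neutrals = vapply(edges, function(e) e$neutrals, ""),
      delta_mz = vapply(edges, function(e) e$delta_mz, 0),
      enthalpy = vapply(edges, function(e) e$enthalpy, 0))
  }
  edge_tbl <- dplyr::distinct(edge_tbl)
  structure(list(nodes = node_tbl, edges = edge_tbl,
                 roots = unname(as.integer(id_of[roots])),
                 ions = stats::setNames(lapply(recs, function(r) r$ion), NULL),
                 config = config, config_hash = config_hash(config)),
            class = "frag_tree")
}

#' @export
print.frag_tree <- function(x, ...) {
  cat(sprintf("<frag_tree> %d ions, %d edges, %d root protomer(s), %d stage(s)\n",
              nrow(x$nodes), nrow(x$edges), length(x$roots),
              max(x$nodes$stage %||% 0)))
  invisible(x)
}

#' Tidy a fragmentation tree into its node table
#' @param x a `frag_tree`.
#' @param ... unused.
#' @return Tibble with one row per ion (formula, m/z, stage, heat of
#'   formation, charge/radical state).
#' @export
tidy.frag_tree <- function(x, ...) x$nodes

#' One-row summary of a fragmentation tree
#' @param x a `frag_tree`.
#' @param ... unused.
#' @export
glance.frag_tree <- function(x, ...) {
  tibble(n_ions = nrow(x$nodes), n_edges = nrow(x$edges),
         n_roots = length(x$roots),
         max_stage = if (nrow(x$nodes)) max(x$nodes$stage) else 0L,
         precursor_mz = if (length(x$roots)) x$nodes$mz[x$roots[1]] else NA_real_,
         config_hash = x$config_hash)
}

# ---- serialization -------------------------------------------------------

#' Write a fragmentation tree to JSON
#'
#' Nodes, edges, roots and provenance (configuration + hash) with
#' full-precision m/z values.
#'
#' @param tree a `frag_tree`.
#' @param path output path.
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(format = "cidfrag_tree", version = 1L,
              config = unclass(tree$config), config_hash = tree$config_hash,
              roots = tree$roots, nodes = tree$nodes, edges = tree$edges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a fragmentation tree from JSON
#'
#' Restores the node/edge tables, roots and configuration written by
#' [write_tree_json()] (molecular graphs are not serialized; annotation and
#' scoring only require the tabular form).
#'
#' @param path JSON file.
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cidfrag_tree")) {
    abort("not a cidfrag tree JSON file", class = "cidfrag_format_error")
  }
  cfg <- obj$config
  config <- engine_config(cfg$max_depth, cfg$enthalpy_window, cfg$window_scope,
                          cfg$max_ions_per_level, cfg$rearrangement_cap,
                          cfg$max_rearrangement_rounds, cfg$weak_bond_threshold,
                          cfg$backend, cfg$seed)
  structure(list(nodes = as_tibble(obj$nodes), edges = as_tibble(obj$edges),
                 roots = obj$roots, ions = NULL, config = config,
                 config_hash = obj$config_hash),
            class = "frag_tree")
}

#' Write a fragmentation tree in DOT format for rendering
#' @param tree a `frag_tree`.
#' @param path output path.
#' @export
write_tree_dot <- function(tree, path) {
  lines <- c("digraph fragmentation {",
             sprintf("  // config %s", tree$config_hash),
             "  node [shape=box];")
  for (i in seq_len(nrow(tree$nodes))) {
    lines <- c(lines, sprintf('  n%d [label="%s\\nm/z %.2f"];',
                              tree$nodes$id[i], tree$nodes$formula[i],
                              tree$nodes$mz[i]))
  }
  for (k in seq_len(nrow(tree$edges))) {
    e <- tree$edges[k, ]
    lab <- if (nzchar(e$neutrals)) sprintf("%s\\n-%s", e$rule, e$neutrals) else e$rule
    lines <- c(lines, sprintf('  n%d -> n%d [label="%s"];',
                              e$parent, e$child, lab))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
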