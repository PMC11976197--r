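# Fragmentation rules: declarative registry + generic executor.
#
# A rule is data: one or more SMARTS-subset trigger patterns, a per-trigger
# label map (symbol -> pattern atom position), and an ordered edit script
# over a closed opcode vocabulary.  The executor turns (ion, rule, embedding)
# into product ions plus neutral losses; every application conserves atoms
# and net charge, which apply_rule() verifies.

#' Construct an ion species
#'
#' @param graph a `molgraph` with |net charge| = 1 (singly charged ESI ions)
#'   or 0 for neutral reference species.
#' @param label free-text label.
#' @param provenance `"root"` or list(parent =, rule =).
#' @return An `ion_species` with fields graph, formula, mz, key, label,
#'   provenance.
#' @export
ion_species <- function(graph, label = "", provenance = "root") {
  f <- formula_of(graph)
  if (abs(f$charge) > 1) {
    abort("only singly charged ions are supported", class = "cidfrag_ion_error")
  }
  structure(list(graph = graph, formula = f,
                 mz = monoisotopic_mz(f),
                 key = canonical_key(graph),
                 label = label, provenance = provenance),
            class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion> %s m/z %.4f %s\n", format(x$formula), x$mz,
              if (nzchar(x$label)) paste0("[", x$label, "]") else ""))
  invisible(x)
}

.edit_opcodes <- c("CLEAVE_BOND", "FORM_BOND", "INC_CHARGE", "DEC_CHARGE",
                   "MOVE_H", "SET_RADICAL", "SPLIT_COMPONENTS")

#' Construct a graph edit
#'
#' @param opcode one of CLEAVE_BOND, FORM_BOND, INC_CHARGE, DEC_CHARGE,
#'   MOVE_H, SET_RADICAL, SPLIT_COMPONENTS.
#' @param a,b atom labels (symbols resolved through the rule's label map).
#' @param order bond order for FORM_BOND (sets the order of an existing bond
#'   or creates the bond).
#' @param kind for MOVE_H: "proton" or "hydride" (audit metadata; charges
#'   are tracked by explicit INC/DEC edits).
#' @param n unpaired electron count for SET_RADICAL.
#' @export
graph_edit <- function(opcode, a = NULL, b = NULL, order = NULL,
                       kind = NULL, n = 1L) {
  if (!opcode %in% .edit_opcodes) {
    abort(paste0("unknown opcode: ", opcode), class = "cidfrag_rule_error")
  }
  list(opcode = opcode, a = a, b = b, order = order, kind = kind, n = n)
}

#' Construct a fragmentation rule
#'
#' @param id rule identifier.
#' @param kind "cleavage" or "rearrangement".
#' @param triggers character vector of SMARTS-subset patterns; the rule fires
#'   on every embedding of every trigger.
#' @param labels list (one per trigger) of named integer vectors mapping
#'   edit symbols to pattern atom positions.
#' @param edits list of [graph_edit()]s, executed in order.
#' @param name,note human-readable name and literature/scheme note.
#' @export
frag_rule <- function(id, kind = c("cleavage", "rearrangement"),
                      triggers, labels, edits, name = id, note = "") {
  kind <- match.arg(kind)
  if (length(labels) != length(triggers)) {
    abort("need one label map per trigger", class = "cidfrag_rule_error")
  }
  structure(list(id = id, kind = kind, triggers = triggers,
                 labels = labels, edits = edits, name = name, note = note),
            class = "frag_rule")
}

#' @export
print.frag_rule <- function(x, ...) {
  cat(sprintf("<rule %s> (%s) %s\n  triggers: %s\n", x$id, x$kind, x$name,
              paste(x$triggers, collapse = " ; ")))
  invisible(x)
}

# resolve symbol -> graph atom index
resolve_label <- function(sym, labmap, mapping) {
  pos <- labmap[[sym]]
  if (is.null(pos) || is.na(pos)) {
    abort(paste0("edit references unknown label: ", sym),
          class = "cidfrag_rule_error")
  }
  unname(mapping[pos])
}

find_bond <- function(g, a, b) {
  which((g$bonds$a1 == a & g$bonds$a2 == b) | (g$bonds$a1 == b & g$bonds$a2 == a))
}

# execute an edit script on a copy of `graph`; returns list(graph, split)
execute_edits <- function(graph, edits, labmap, mapping, rule_id = "?") {
  g <- graph
  split <- FALSE
  fail <- function(msg) {
    abort(sprintf("rule '%s' failed on mapping [%s]: %s", rule_id,
                  paste(mapping, collapse = ","), msg),
          class = "cidfrag_rule_execution_error")
  }
  for (e in edits) {
    if (e$opcode == "SPLIT_COMPONENTS") { split <- TRUE; next }
    a <- if (!is.null(e$a)) resolve_label(e$a, labmap, mapping)
    b <- if (!is.null(e$b)) resolve_label(e$b, labmap, mapping)
    if (e$opcode == "CLEAVE_BOND") {
      k <- find_bond(g, a, b)
      if (length(k) != 1) fail(sprintf("no bond %d-%d to cleave", a, b))
      g$bonds <- g$bonds[-k, , drop = FALSE]
    } else if (e$opcode == "FORM_BOND") {
      k <- find_bond(g, a, b)
      if (length(k) == 1) {
        g$bonds$order[k] <- as.integer(e$order)
        g$bonds$aromatic[k] <- FALSE
      } else {
        g$bonds <- rbind(g$bonds, data.frame(a1 = a, a2 = b,
                                             order = as.integer(e$order),
                                             aromatic = FALSE))
      }
    } else if (e$opcode == "INC_CHARGE") {
      g$atoms$charge[a] <- g$atoms$charge[a] + 1L
    } else if (e$opcode == "DEC_CHARGE") {
      g$atoms$charge[a] <- g$atoms$charge[a] - 1L
    } else if (e$opcode == "MOVE_H") {
      if (g$atoms$hcount[a] < 1) fail(sprintf("atom %d has no H to move", a))
      g$atoms$hcount[a] <- g$atoms$hcount[a] - 1L
      g$atoms$hcount[b] <- g$atoms$hcount[b] + 1L
    } else if (e$opcode == "SET_RADICAL") {
      g$atoms$nrad[a] <- as.integer(e$n)
    }
  }
  list(graph = g, split = split)
}

#' Apply a fragmentation rule to an ion
#'
#' One application per trigger embedding; products are validated (valence,
#' atom and charge conservation) and deduplicated by canonical key.  A
#' failing edit script on a matched embedding raises a rule-execution error
#' naming the rule and mapping; it is never silently skipped.
#'
#' @param ion an `ion_species`.
#' @param rule a `frag_rule`.
#' @param ctx optional precomputed matching context (internal use).
#' @return List of `rule_application` objects: fields `rule_id`, `mapping`,
#'   `ion` (charged product), `neutrals` (list of neutral `molgraph`s),
#'   `delta_mz`, `is_cleavage` (TRUE when neutrals are lost).
#' @export
apply_rule <- function(ion, rule, ctx = NULL) {
  stopifnot(inherits(ion, "ion_species"), inherits(rule, "frag_rule"))
  if (is.null(ctx)) ctx <- make_match_ctx(ion$graph)
  out <- list()
  seen <- character(0)
  for (t in seq_along(rule$triggers)) {
    maps <- match_pattern(ion$graph, rule$triggers[t], ctx = ctx)
    for (m in maps) {
      ex <- execute_edits(ion$graph, rule$edits, rule$labels[[t]], m, rule$id)
      parts <- if (ex$split) graph_components(ex$graph) else
        list(perceive_aromaticity(ex$graph))
      chg <- vapply(parts, net_charge, 0L)
      if (sum(chg == 1L) != 1 || any(!chg %in% c(0L, 1L))) {
        abort(sprintf("rule '%s' on mapping [%s]: products must be one +1 ion plus neutrals (got charges %s)",
                      rule$id, paste(m, collapse = ","),
                      paste(chg, collapse = ",")),
              class = "cidfrag_rule_execution_error")
      }
      for (p in parts) validate_molgraph(p)
      # conservation
      total <- sum_formulas(lapply(parts, formula_of))
      parent_f <- ion$formula
      if (!identical(total$counts, parent_f$counts) ||
          total$charge != parent_f$charge) {
        abort(sprintf("rule '%s' violates conservation on mapping [%s]",
                      rule$id, paste(m, collapse = ",")),
              class = "cidfrag_rule_execution_error")
      }
      prod_ion <- ion_species(parts[[which(chg == 1L)]],
                              provenance = list(parent = ion$key, rule = rule$id))
      neutrals <- parts[chg == 0L]
      key <- paste(prod_ion$key,
                   paste(sort(vapply(neutrals, canonical_key, "")), collapse = ";"))
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1]] <- structure(
        list(rule_id = rule$id, mapping = m, ion = prod_ion,
             neutrals = neutrals, delta_mz = ion$mz - prod_ion$mz,
             is_cleavage = length(neutrals) > 0),
        class = "rule_application")
    }
  }
  out
}

#' Execute the steroid methyl-shift rearrangement on a given embedding
#'
#' Runs exactly the four edit steps of the C/D-ring methyl-shift
#' (Wagner-Meerwein) rule: (1) the bond between the methyl group and the
#' ring-fusion carbon is cleaved; (2) a new single bond is formed between
#' the methyl group and the charged ring carbon; (3) the charge of the
#' charged atom is reduced by one; (4) the charge of the former
#' methyl-bearing carbon is increased by one.
#'
#' @param ion an `ion_species` matching one of the methyl-shift triggers.
#' @param mapping an embedding (named integer vector) as returned by
#'   [match_pattern()] for one of the rule's triggers.
#' @return The rearranged `ion_species` (same formula and m/z, tertiary
#'   carbocation at the former methyl-bearing ring-fusion carbon).
#' @export
apply_methyl_shift <- function(ion, mapping) {
  rule <- builtin_registry()[["methyl_shift"]]
  t_idx <- NULL
  for (t in seq_along(rule$triggers)) {
    maps <- match_pattern(ion$graph, rule$triggers[t])
    if (any(vapply(maps, function(m) identical(unname(m), unname(mapping)), TRUE))) {
      t_idx <- t; break
    }
  }
  if (is.null(t_idx)) {
    abort("mapping is not an embedding of a methyl-shift trigger",
          class = "cidfrag_precondition_error")
  }
  ex <- execute_edits(ion$graph, rule$edits, rule$labels[[t_idx]], mapping,
                      rule$id)
  g <- perceive_aromaticity(ex$graph)
  validate_molgraph(g)
  ion_species(g, provenance = list(parent = ion$key, rule = rule$id))
}

# ---- built-in registry ---------------------------------------------------

#' Built-in fragmentation rule registry
#'
#' Cleavage and rearrangement rules whose action reproduces the worked
#' ESI(+) pathways shipped as fixtures: steroid methyl shift, water
#' elimination from protonated hydroxyls, proton transfers to heteroatoms,
#' 1,2-hydride and 1,3-allyl shifts, ring opening and acyclic beta-scission
#' at carbocations, retro-Diels-Alder cleavage, McLafferty-type alkene
#' eliminations on esters (acid and alcohol side), Alk-O ester cleavage,
#' HCN loss (aliphatic nitrile and protonated azine ring), NH3/HNCO/CO
#' losses of amides and acylium ions, and homolytic methyl-radical loss.
#' The set is user-extensible: rules are plain data ([frag_rule()]) and can
#' be loaded from a YAML rules file ([read_rules()]).
#'
#' @return Named list of `frag_rule` objects.
#' @export
builtin_registry <- function() {
  r <- list()

  r$methyl_shift <- frag_rule(
    "methyl_shift", "rearrangement",
    triggers = c("[CH3]C12CCCC1CC[C+]2", "[CH3]C12CCCCC1CC[C+]2"),
    labels = list(c(me = 1L, c1 = 2L, cp = 9L),
                  c(me = 1L, c1 = 2L, cp = 10L)),
    edits = list(graph_edit("CLEAVE_BOND", "me", "c1"),
                 graph_edit("FORM_BOND", "me", "cp", order = 1),
                 graph_edit("DEC_CHARGE", "cp"),
                 graph_edit("INC_CHARGE", "c1")),
    name = "1,2-methyl shift (Wagner-Meerwein), steroid C/D rings",
    note = "tertiary carbocation from C-13/C-17-type methyl migration")

  r$water_loss <- frag_rule(
    "water_loss", "cleavage",
    triggers = "[C][OH2+]",
    labels = list(c(c = 1L, o = 2L)),
    edits = list(graph_edit("CLEAVE_BOND", "c", "o"),
                 graph_edit("DEC_CHARGE", "o"),
                 graph_edit("INC_CHARGE", "c"),
                 graph_edit("SPLIT_COMPONENTS")),
    name = "water elimination from a protonated hydroxyl",
    note = "neutral loss H2O")

  pt_edits <- list(graph_edit("MOVE_H", "d", "acc", kind = "proton"),
                   graph_edit("DEC_CHARGE", "d"),
                   graph_edit("INC_CHARGE", "acc"))
  r$proton_transfer <- frag_rule(
    "proton_transfer", "rearrangement",
    triggers = c("[OH2+].[NX1]#C", "[OH+].[NX1]#C", "[OH2+].[nX2]",
                 "[NH3+].[nX2]", "[OH2+].[O]=[CX3]", "[OH2+].[NX3]"),
    labels = rep(list(c(d = 1L, acc = 2L)), 6),
    edits = pt_edits,
    name = "intramolecular proton transfer between heteroatoms",
    note = "includes transfer to nitrile N and azine N")

  r$hydride_shift <- frag_rule(
    "hydride_shift", "rearrangement",
    triggers = c("[CH3][C+]", "[CH2][C+]", "[CH1][C+]"),
    labels = rep(list(c(d = 1L, cp = 2L)), 3),
    edits = list(graph_edit("MOVE_H", "d", "cp", kind = "hydride"),
                 graph_edit("INC_CHARGE", "d"),
                 graph_edit("DEC_CHARGE", "cp")),
    name = "1,2-hydride shift to an adjacent carbocation")

  r$allyl_shift <- frag_rule(
    "allyl_shift", "rearrangement",
    triggers = "[C+]-[C]=[C]",
    labels = list(c(c1 = 1L, c2 = 2L, c3 = 3L)),
    edits = list(graph_edit("FORM_BOND", "c1", "c2", order = 2),
                 graph_edit("FORM_BOND", "c2", "c3", order = 1),
                 graph_edit("DEC_CHARGE", "c1"),
                 graph_edit("INC_CHARGE", "c3")),
    name = "allylic rearrangement (1,3 shift of the charge)")

  ring_edits <- list(graph_edit("CLEAVE_BOND", "ca", "cb"),
                     graph_edit("FORM_BOND", "cp", "ca", order = 2),
                     graph_edit("DEC_CHARGE", "cp"),
                     graph_edit("INC_CHARGE", "cb"))
  r$ring_opening <- frag_rule(
    "ring_opening", "rearrangement",
    triggers = "[C+]-[C]-@[C]",
    labels = list(c(cp = 1L, ca = 2L, cb = 3L)),
    edits = ring_edits,
    name = "ring opening adjacent to a carbocation (endocyclic beta-scission)")

  r$beta_scission <- frag_rule(
    "beta_scission", "cleavage",
    triggers = "[C+]-[C]-!@[C]",
    labels = list(c(cp = 1L, ca = 2L, cb = 3L)),
    edits = c(ring_edits, list(graph_edit("SPLIT_COMPONENTS"))),
    name = "acyclic beta-scission (alkene loss / charge relocation)")

  r$retro_diels_alder <- frag_rule(
    "retro_diels_alder", "cleavage",
    triggers = "[C]1=[C]-@[C]-@[C]-@[C]-@[C]-@1",
    labels = list(c(r1 = 1L, r2 = 2L, r3 = 3L, r4 = 4L, r5 = 5L, r6 = 6L)),
    edits = list(graph_edit("CLEAVE_BOND", "r3", "r4"),
                 graph_edit("CLEAVE_BOND", "r5", "r6"),
                 graph_edit("FORM_BOND", "r6", "r1", order = 2),
                 graph_edit("FORM_BOND", "r2", "r3", order = 2),
                 graph_edit("FORM_BOND", "r1", "r2", order = 1),
                 graph_edit("FORM_BOND", "r4", "r5", order = 2),
                 graph_edit("SPLIT_COMPONENTS")),
    name = "retro-Diels-Alder cleavage of a cyclohexene ring")

  r$mclafferty <- frag_rule(
    "mclafferty", "cleavage",
    triggers = "[CX3](=O)[C][CH2][CH3]",
    labels = list(c(cc = 1L, o = 2L, ca = 3L, cb = 4L, cg = 5L)),
    edits = list(graph_edit("MOVE_H", "cg", "o", kind = "proton"),
                 graph_edit("CLEAVE_BOND", "ca", "cb"),
                 graph_edit("FORM_BOND", "cb", "cg", order = 2),
                 graph_edit("FORM_BOND", "cc", "ca", order = 2),
                 graph_edit("FORM_BOND", "cc", "o", order = 1),
                 graph_edit("SPLIT_COMPONENTS")),
    name = "McLafferty-type alkene elimination (acid side, gamma-H to carbonyl O)")

  r$alk_o_cleavage <- frag_rule(
    "alk_o_cleavage", "cleavage",
    triggers = "[C,c][OX2][CH2][CH3]",
    labels = list(c(c = 1L, o = 2L, cb = 3L, cg = 4L)),
    edits = list(graph_edit("MOVE_H", "cg", "o", kind = "proton"),
                 graph_edit("CLEAVE_BOND", "o", "cb"),
                 graph_edit("FORM_BOND", "cb", "cg", order = 2),
                 graph_edit("SPLIT_COMPONENTS")),
    name = "Alk-O ester cleavage / alcohol-side alkene elimination",
    note = "protonated acid + alkene from ethyl esters")

  r$hcn_loss <- frag_rule(
    "hcn_loss", "cleavage",
    triggers = c("[CH2][C+][CH2]C#N", "[CH3][C+][CH2]C#N", "[CH1][C+][CH2]C#N"),
    labels = rep(list(c(d = 1L, a = 2L, b = 3L, cn = 4L, n = 5L)), 3),
    edits = list(graph_edit("MOVE_H", "d", "cn", kind = "proton"),
                 graph_edit("FORM_BOND", "d", "a", order = 2),
                 graph_edit("CLEAVE_BOND", "b", "cn"),
                 graph_edit("DEC_CHARGE", "a"),
                 graph_edit("INC_CHARGE", "b"),
                 graph_edit("SPLIT_COMPONENTS")),
    name = "HCN loss from a nitrile alpha to a carbocation",
    note = "proton transfer + C-CN cleavage; allylic product cation")

  r$nh3_loss <- frag_rule(
    "nh3_loss", "cleavage",
    triggers = "[CX3](=O)[NH3+]",
    labels = list(c(c = 1L, o = 2L, n = 3L)),
    edits = list(graph_edit("CLEAVE_BOND", "c", "n"),
                 graph_edit("DEC_CHARGE", "n"),
                 graph_edit("INC_CHARGE", "c"),
                 graph_edit("SPLIT_COMPONENTS")),
    name = "NH3 loss from an N-protonated amide (acylium product)")

  r$hnco_loss <- frag_rule(
    "hnco_loss", "cleavage",
    triggers = "[c][CX3](=O)[NH2]",
    labels = list(c(ar = 1L, c = 2L, o = 3L, n = 4L)),
    edits = list(graph_edit("MOVE_H", "n", "ar", kind = "proton"),
                 graph_edit("CLEAVE_BOND", "ar", "c"),
                 graph_edit("FORM_BOND", "c", "n", order = 2),
                 graph_edit("SPLIT_COMPONENTS")),
    name = "HNCO loss from an aryl amide")

  r$co_loss <- frag_rule(
    "co_loss", "cleavage",
    triggers = "[#6][C+]=[O]",
    labels = list(c(r = 1L, c = 2L, o = 3L)),
    edits = list(graph_edit("CLEAVE_BOND", "r", "c"),
                 graph_edit("FORM_BOND", "c", "o", order = 3),
                 graph_edit("DEC_CHARGE", "c"),
                 graph_edit("DEC_CHARGE", "c"),
                 graph_edit("INC_CHARGE", "o"),
                 graph_edit("INC_CHARGE", "r"),
                 graph_edit("SPLIT_COMPONENTS")),
    name = "CO loss from an acylium ion")

  r$azine_hcn_loss <- frag_rule(
    "azine_hcn_loss", "cleavage",
    triggers = "[nH+]1:[cH]:[c]:[c]:[c]:[cH]:1",
    labels = list(c(n1 = 1L, c2 = 2L, c3 = 3L, c4 = 4L, c5 = 5L, c6 = 6L)),
    edits = list(graph_edit("MOVE_H", "n1", "c6", kind = "proton"),
                 graph_edit("CLEAVE_BOND", "n1", "c6"),
                 graph_edit("CLEAVE_BOND", "c2", "c3"),
                 graph_edit("FORM_BOND", "n1", "c2", order = 3),
                 graph_edit("FORM_BOND", "c6", "c5", order = 2),
                 graph_edit("FORM_BOND", "c5", "c4", order = 1),
                 graph_edit("FORM_BOND", "c4", "c3", order = 2),
                 graph_edit("DEC_CHARGE", "n1"),
                 graph_edit("INC_CHARGE", "c3"),
                 graph_edit("SPLIT_COMPONENTS")),
    name = "HCN loss from a protonated azine ring (retro-[4+2]-type)")

  r$methyl_radical_loss <- frag_rule(
    "methyl_radical_loss", "cleavage",
    triggers = "[CH3][CX4]([#6])[#6]",
    labels = list(c(me = 1L, c = 2L)),
    edits = list(graph_edit("CLEAVE_BOND", "me", "c"),
                 graph_edit("SET_RADICAL", "me", n = 1),
                 graph_edit("SET_RADICAL", "c", n = 1),
                 graph_edit("SPLIT_COMPONENTS")),
    name = "homolytic methyl-radical loss (distonic radical cation product)")

  r
}

# ---- rules file I/O and validation --------------------------------------

#' Write a rule registry to a YAML rules file
#' @param rules named list of `frag_rule`s.
#' @param path output file.
#' @export
write_rules <- function(rules, path) {
  doc <- lapply(unname(rules), function(r) {
    list(id = r$id, kind = r$kind, name = r$name, note = r$note,
         triggers = as.list(r$triggers),
         labels = lapply(r$labels, as.list),
         edits = lapply(r$edits, function(e) Filter(Negate(is.null), e)))
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a rule registry from a YAML rules file
#' @param path rules file written by [write_rules()] (or hand-authored).
#' @export
read_rules <- function(path) {
  doc <- yaml::read_yaml(path)
  rules <- lapply(doc, function(d) {
    frag_rule(d$id, d$kind, unlist(d$triggers),
              labels = lapply(d$labels, function(l) unlist(l)),
              edits = lapply(d$edits, function(e) {
                graph_edit(e$opcode, a = e$a, b = e$b, order = e$order,
                           kind = e$kind, n = e$n %||% 1L)
              }),
              name = d$name %||% d$id, note = d$note %||% "")
  })
  stats::setNames(rules, vapply(rules, function(r) r$id, ""))
}

#' Validate a rule registry
#'
#' Static checks: known opcodes, edit labels resolvable in every trigger's
#' label map, balanced charge edits (equal INC/DEC counts).  Dynamic checks
#' (when ions are supplied): every application on every ion conserves atoms
#' and charge and yields valence-valid products.
#'
#' @param rules named list of `frag_rule`s.
#' @param ions optional list of `ion_species` to exercise the rules on.
#' @return A tibble of diagnostics (zero rows = all checks passed).
#' @export
validate_rules <- function(rules, ions = list()) {
  bad <- list()
  note <- function(rule, check, msg) {
    bad[[length(bad) + 1]] <<- tibble(rule = rule, check = check, message = msg)
  }
  for (r in rules) {
    ops <- vapply(r$edits, function(e) e$opcode, "")
    if (!all(ops %in% .edit_opcodes)) {
      note(r$id, "opcodes", paste("unknown opcode:",
                                  paste(setdiff(ops, .edit_opcodes), collapse = ",")))
    }
    if (sum(ops == "INC_CHARGE") != sum(ops == "DEC_CHARGE")) {
      note(r$id, "charge_balance", "unbalanced INC_CHARGE/DEC_CHARGE edits")
    }
    syms <- unique(unlist(lapply(r$edits, function(e) c(e$a, e$b))))
    for (t in seq_along(r$triggers)) {
      pat <- tryCatch(parse_smarts(r$triggers[t]), error = function(e) NULL)
      if (is.null(pat)) { note(r$id, "trigger", paste("unparsable trigger", t)); next }
      lm <- r$labels[[t]]
      missing <- setdiff(syms, names(lm))
      if (length(missing) > 0) {
        note(r$id, "labels", paste("unresolved labels in trigger", t, ":",
                                   paste(missing, collapse = ",")))
      } else if (any(lm[syms] > length(pat$atoms))) {
        note(r$id, "labels", paste("label beyond pattern size in trigger", t))
      }
    }
    for (ion in ions) {
      res <- tryCatch({ apply_rule(ion, r); NULL }, error = function(e) e)
      if (!is.null(res)) {
        note(r$id, "dynamic", conditionMessage(res))
      }
    }
  }
  if (length(bad) == 0) {
    tibble(rule = character(0), check = character(0), message = character(0))
  } else dplyr::bind_rows(bad)
}
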