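# External semiempirical backend (MOPAC/PM7).
#
# Opt-in: the engine's default heuristic backend needs no external software.
# When a MOPAC executable is configured, graphs are embedded in 3D (OpenBabel
# gen3D, seeded), a PM7 input deck is written, and the final heat of
# formation and bond-order block are parsed from the output file.  Results
# are cached by canonical key inside make_evaluator().

#' Write a PM7 input deck for a molecular graph
#'
#' Keyword line (PM7, charge, multiplicity, BONDS for the bond-order block)
#' followed by Cartesian coordinates from a deterministic seeded 3D
#' embedding.
#'
#' @param graph a `molgraph`.
#' @param path output file.
#' @param seed conformer-generator seed (recorded in a comment line).
#' @export
write_mopac_deck <- function(graph, path, seed = 1L) {
  mult <- if (is_radical(graph)) "DOUBLET" else "SINGLET"
  kw <- sprintf("PM7 1SCF CHARGE=%d %s BONDS", net_charge(graph), mult)
  xyz <- embed_3d(graph, seed)
  lines <- c(kw,
             sprintf("cidfrag deck (seed %d)", seed),
             "",
             sprintf("%-2s %12.5f 1 %12.5f 1 %12.5f 1",
                     graph$atoms$element, xyz[, 1], xyz[, 2], xyz[, 3]))
  writeLines(lines, path)
  invisible(path)
}

# 3D embedding via OpenBabel; falls back to a deterministic circular layout
# if the toolkit cannot embed the graph
embed_3d <- function(graph, seed = 1L) {
  n <- n_atoms(graph)
  coords <- tryCatch({
    txt <- ChemmineOB::convertFormat("SDF", "SDF", write_molblock(graph),
                                     options = data.frame(names = "gen3D",
                                                          args = ""))
    mb <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    t(vapply(seq_len(n), function(i) {
      ln <- mb[4 + i]
      c(as.numeric(substr(ln, 1, 10)), as.numeric(substr(ln, 11, 20)),
        as.numeric(substr(ln, 21, 30)))
    }, numeric(3)))
  }, error = function(e) NULL)
  if (is.null(coords) || anyNA(coords)) {
    ang <- 2 * pi * (seq_len(n) + seed %% 7) / n
    coords <- cbind(1.5 * cos(ang), 1.5 * sin(ang), 0.1 * seq_len(n))
  }
  coords
}

#' Parse a MOPAC output file
#'
#' Extracts the final heat of formation (kcal/mol) and the bond-order block.
#'
#' @param path MOPAC .out file.
#' @param graph the evaluated `molgraph` (to index bond orders).
#' @return An `energy_result` (converged = FALSE when the normal-termination
#'   heat-of-formation line is absent).
#' @export
parse_mopac_output <- function(path, graph) {
  lines <- readLines(path, warn = FALSE)
  hline <- grep("FINAL HEAT OF FORMATION", lines, value = TRUE)
  if (length(hline) == 0) {
    abort("MOPAC output is missing the 'FINAL HEAT OF FORMATION' field",
          class = "cidfrag_external_error")
  }
  hof <- as.numeric(sub(".*FINAL HEAT OF FORMATION\\s*=\\s*(-?[0-9.]+).*", "\\1",
                        hline[1]))
  if (is.na(hof)) {
    abort("cannot parse heat of formation value from MOPAC output",
          class = "cidfrag_external_error")
  }
  # bond-order block: lines "  <i>  <j>  <order>" after the BOND ORDERS header
  bo <- rep(NA_real_, nrow(graph$bonds))
  hdr <- grep("BOND ORDERS", lines)
  if (length(hdr) > 0) {
    for (ln in lines[(hdr[1] + 1):length(lines)]) {
      m <- regmatches(ln, regexec("^\\s*(\\d+)\\s+(\\d+)\\s+(-?[0-9.]+)\\s*$", ln))[[1]]
      if (length(m) == 0) next
      i <- as.integer(m[2]); j <- as.integer(m[3])
      k <- find_bond(graph, i, j)
      if (length(k) == 1) bo[k] <- as.numeric(m[4])
    }
  }
  if (anyNA(bo)) bo[is.na(bo)] <- as.numeric(graph$bonds$order[is.na(bo)])
  structure(list(hof = hof, bond_orders = bo, converged = TRUE,
                 backend = "external"), class = "energy_result")
}

#' Evaluate a graph with an external semiempirical program
#'
#' Writes a PM7 deck, invokes the program and parses heat of formation and
#' bond orders.  Non-convergence yields `converged = FALSE` with a large
#' fallback heat of formation (candidates are kept, not silently pruned).
#'
#' @param graph a `molgraph`.
#' @param mopac_path path to the MOPAC executable.
#' @param workdir scratch directory for decks and outputs.
#' @param seed 3D-embedding seed.
#' @param timeout seconds before the run is abandoned as non-converged.
#' @export
evaluate_external <- function(graph, mopac_path = Sys.which("mopac"),
                              workdir = tempdir(), seed = 1L, timeout = 120) {
  if (!nzchar(mopac_path) || !file.exists(mopac_path)) {
    abort(paste0("external program not found (looked for '", mopac_path, "'); ",
                 "install MOPAC and set mopac_path, or use the heuristic backend"),
          class = "cidfrag_config_error")
  }
  deck <- file.path(workdir, paste0("cidfrag-", rlang::hash(canonical_key(graph)),
                                    ".mop"))
  write_mopac_deck(graph, deck, seed = seed)
  status <- tryCatch(
    system2(mopac_path, deck, stdout = FALSE, stderr = FALSE, timeout = timeout),
    warning = function(w) -1L, error = function(e) -1L)
  out <- sub("\\.mop$", ".out", deck)
  if (status != 0L || !file.exists(out)) {
    return(structure(list(hof = 1e4, bond_orders = as.numeric(graph$bonds$order),
                          converged = FALSE, backend = "external"),
                     class = "energy_result"))
  }
  parse_mopac_output(out, graph)
}
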