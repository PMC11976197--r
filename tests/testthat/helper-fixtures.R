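# Shared lazily-built objects.  Fragmentation trees for the larger steroids
# take tens of seconds, so each is computed once per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture_smiles <- function(label) {
  fx <- fixture_compounds()
  fx$smiles[fx$label == label]
}

fixture_graph <- function(label) {
  key <- paste0("g", label)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- parse_structure(fixture_smiles(label))
  }
  .fixture_env[[key]]
}

fixture_tree <- function(label, config = engine_config()) {
  key <- paste0("t", label)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- fragment(fixture_graph(label), config)
  }
  .fixture_env[[key]]
}

# protonated 17-OH species of a steroid fixture: the protomer from which a
# water-loss rule application exists
oh17_protomer <- function(label) {
  pr <- ionize(fixture_graph(label))
  for (p in pr) {
    if (length(apply_rule(p, builtin_registry()$water_loss)) > 0) return(p)
  }
  stop("no aliphatic-OH protomer found")
}

expect_formula <- function(graph, formula_string) {
  expect_identical(format(formula_of(graph)), formula_string)
}
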