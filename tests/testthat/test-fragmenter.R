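test_that("ionization protonates every basic heteroatom site", {
  pr <- ionize(fixture_graph("1"))
  expect_length(pr, 2)                                # 3-OH and 17-OH
  expect_true(all(vapply(pr, function(p) format(p$formula), "") == "C18H25O2+"))
  expect_equal(length(unique(round(vapply(pr, function(p) p$mz, 0), 6))), 1)

  pr3 <- ionize(fixture_graph("3"))
  expect_length(pr3, 3)                               # 2x OH + nitrile N
  expect_true(any(vapply(pr3, function(p)
    length(apply_rule(p, builtin_registry()$water_loss)) > 0, TRUE)))

  expect_warning(pr0 <- ionize(parse_structure("C")), "no protonation site")
  expect_length(pr0, 0)
})

test_that("stability selection applies window then deterministic cap", {
  cfg <- engine_config(enthalpy_window = 5, max_ions_per_level = 10)
  cand <- tibble::tibble(key = c("a", "b"), enthalpy = c(0, 10),
                         parent_key = "p", app = list(NULL, NULL))
  expect_identical(select_stable(cand, cfg)$key, "a")
  cfg0 <- engine_config(enthalpy_window = 0, max_ions_per_level = 10)
  cand2 <- tibble::tibble(key = letters[1:4], enthalpy = rep(2, 4),
                          parent_key = "p", app = list(NULL, NULL, NULL, NULL))
  expect_equal(nrow(select_stable(cand2, cfg0)), 4)
  cfgInf <- engine_config(enthalpy_window = Inf, max_ions_per_level = 2)
  expect_equal(nrow(select_stable(cand2, cfgInf)), 2)
})

test_that("depth-one trees contain only the protomer roots", {
  tree <- fragment(fixture_graph("5"), engine_config(max_depth = 1))
  expect_equal(nrow(tree$nodes), length(tree$roots))
  expect_true(all(tree$nodes$stage == 0))
  expect_equal(nrow(tree$edges), 0)
})

test_that("a molecule without protonation sites yields an empty tree", {
  expect_warning(tree <- fragment(parse_structure("C1CCCCC1")))
  expect_equal(nrow(tree$nodes), 0)
  expect_length(tree$roots, 0)
})

test_that("expansion contains the documented channels", {
  e2 <- apply_rule(oh17_protomer("1"), builtin_registry()$water_loss)[[1]]$ion
  apps <- expand(e2)
  rules <- vapply(apps, function(a) a$rule_id, "")
  expect_true("methyl_shift" %in% rules)
  expect_true("methyl_radical_loss" %in% rules)
  # ammonium has no matching rule or weak bond
  expect_length(expand(ion_species(parse_structure("[NH4+]"))), 0)
})

test_that("trees are deterministic for a fixed configuration", {
  g <- fixture_graph("4")
  t1 <- fragment(g); t2 <- fragment(g)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_tree_json(t1, f1); write_tree_json(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("m/z is non-increasing along paths and conserved at edges", {
  for (lab in c("1", "3", "4", "5")) {
    tree <- fixture_tree(lab)
    e <- tree$edges
    parent_mz <- tree$nodes$mz[e$parent]
    child_mz <- tree$nodes$mz[e$child]
    expect_true(all(child_mz <= parent_mz + 1e-9), info = lab)
    # cleavage edges lose exactly the neutral mass; rearrangements none
    loss <- vapply(seq_len(nrow(e)), function(k) {
      if (!nzchar(e$neutrals[k])) return(0)
      sum(vapply(strsplit(e$neutrals[k], "+", fixed = TRUE)[[1]],
                 function(f) monoisotopic_mz(parse_formula(f)), 0))
    }, 0)
    expect_equal(parent_mz - child_mz, loss, tolerance = 1e-6, info = lab)
    expect_true(all(nzchar(e$neutrals) == (loss > 0)), info = lab)
    # every node singly charged, reachable from a root, graph acyclic
    expect_true(all(tree$nodes$charge == 1L), info = lab)
    ig <- igraph::graph_from_data_frame(e[, 1:2], directed = TRUE,
                                        vertices = tree$nodes$id)
    reach <- unique(unlist(lapply(tree$roots, function(r)
      as.integer(igraph::as_ids(igraph::subcomponent(ig, as.character(r),
                                                     "out"))))))
    expect_setequal(reach, tree$nodes$id)
    expect_true(igraph::is_dag(ig), info = lab)
  }
})

test_that("trees round-trip through JSON and render to DOT", {
  tree <- fixture_tree("4")
  path <- withr::local_tempfile(fileext = ".json")
  write_tree_json(tree, path)
  back <- read_tree_json(path)
  expect_equal(back$nodes$mz, tree$nodes$mz)
  expect_identical(back$nodes$formula, tree$nodes$formula)
  expect_identical(back$edges$rule, tree$edges$rule)
  expect_identical(back$roots, tree$roots)
  expect_identical(back$config_hash, tree$config_hash)
  dot <- withr::local_tempfile(fileext = ".dot")
  write_tree_dot(tree, dot)
  expect_match(readLines(dot)[1], "digraph")
})

test_that("tidy and glance summarise trees", {
  tree <- fixture_tree("5")
  td <- tidy(tree)
  expect_true(all(c("formula", "mz", "stage") %in% names(td)))
  gl <- glance(tree)
  expect_equal(gl$n_ions, nrow(tree$nodes))
  expect_equal(round(gl$precursor_mz, 2), 123.06)
})
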