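test_that("carbocation stability follows the textbook order", {
  ev <- make_evaluator()
  tert <- ev(parse_structure("C[C+](C)C"))$hof
  sec <- ev(parse_structure("C[C+]CC"))$hof
  prim <- ev(parse_structure("[CH2+]CCC"))$hof
  expect_lt(tert, sec)
  expect_lt(sec, prim)
})

test_that("benzylic resonance beats a localized aryl cation of equal formula", {
  ev <- make_evaluator()
  benzyl <- parse_structure("[CH2+]c1ccccc1")      # C7H7+
  tol <- parse_structure("Cc1ccccc1")
  aryl <- tol                                       # methylphenyl cation C7H7+
  i <- which(aryl$atoms$aromatic & aryl$atoms$hcount == 1)[1]
  aryl$atoms$hcount[i] <- 0L
  aryl$atoms$charge[i] <- 1L
  expect_identical(format(formula_of(benzyl)), format(formula_of(aryl)))
  expect_lt(ev(benzyl)$hof, ev(aryl)$hof)
})

test_that("neutral molecules evaluate finite with nominal bond orders", {
  ev <- make_evaluator()
  w <- ev(parse_structure("O"))
  expect_true(is.finite(w$hof) && w$converged)
  eth <- ev(parse_structure("CC"))
  expect_equal(eth$bond_orders, 1)
  benz <- ev(parse_structure("c1ccccc1"))
  expect_true(all(benz$bond_orders == 1.5))
})

test_that("reaction enthalpy of a null rearrangement is zero", {
  ev <- make_evaluator()
  ion <- ion_species(parse_structure("C[C+](C)C"))
  expect_equal(reaction_enthalpy(ion, list(ion$graph), ev), 0)
})

test_that("enthalpy ordering is invariant under an additive constant", {
  shift_base <- heuristic_params()
  shift_base$atom_base <- shift_base$atom_base + 100
  ev1 <- make_evaluator()
  ev2 <- make_evaluator(params = shift_base)
  parent <- oh17_protomer("1")
  apps <- expand(parent, evaluator = ev1)
  dh1 <- vapply(apps, function(a)
    reaction_enthalpy(parent, c(list(a$ion$graph), a$neutrals), ev1), 0)
  dh2 <- vapply(apps, function(a)
    reaction_enthalpy(parent, c(list(a$ion$graph), a$neutrals), ev2), 0)
  expect_identical(order(dh1), order(dh2))
  expect_equal(dh1, dh2, tolerance = 1e-9)  # atom terms cancel exactly
})

test_that("enthalpies add along a two-step path", {
  ev <- make_evaluator()
  p1 <- oh17_protomer("3")
  a1 <- apply_rule(p1, builtin_registry()$water_loss)[[1]]
  d2 <- a1$ion
  a2 <- apply_rule(d2, builtin_registry()$hcn_loss)[[1]]
  h1 <- reaction_enthalpy(p1, c(list(d2$graph), a1$neutrals), ev)
  h2 <- reaction_enthalpy(d2, c(list(a2$ion$graph), a2$neutrals), ev)
  total <- reaction_enthalpy(
    p1, c(list(a2$ion$graph), a2$neutrals, a1$neutrals), ev)
  expect_equal(h1 + h2, total, tolerance = 1e-9)
})

test_that("weak bonds sit alpha/beta to the charge site", {
  ev <- make_evaluator()
  toy <- parse_structure("CC12CCCC1CC[C+]2")
  en <- ev(toy)
  expect_length(weak_bonds(toy, en, threshold = 0), 0)
  expect_equal(length(weak_bonds(toy, en, threshold = 10)),
               sum(!toy$bonds$aromatic))
  wb <- weak_bonds(toy, en, threshold = 0.9)
  expect_gte(length(wb), 1)
  cp <- which(toy$atoms$charge == 1)
  nbr <- unique(c(toy$bonds$a2[toy$bonds$a1 == cp], toy$bonds$a1[toy$bonds$a2 == cp]))
  near <- unique(c(cp, nbr))
  expect_true(all(toy$bonds$a1[wb] %in% near | toy$bonds$a2[wb] %in% near))
  # aromatic bonds are never flagged weak
  est <- fixture_graph("1")
  expect_length(intersect(weak_bonds(est, ev(est), 10), which(est$bonds$aromatic)), 0)
})

test_that("evaluators are deterministic and cached by graph value", {
  ev <- make_evaluator()
  g <- fixture_graph("5")
  expect_identical(ev(g), ev(g))
  expect_identical(ev(g)$backend, "heuristic")
})
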