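# Expected embedding counts were computed once with an independent
# cheminformatics toolkit (uniquify = FALSE semantics: automorphic images
# count separately) and frozen here.

test_that("embedding counts match the independent oracle", {
  cases <- list(
    list("CC12CCCC1CC[C+]2", "[CH3]C12CCCC1CC[C+]2", 1L),
    list("CC12CCC3c4ccc(O)cc4CCC3C1CCC2O", "[CH3]C12CCCC1CC[C+]2", 0L),
    list("CC12CCC3c4ccc(O)cc4CCC3C1CCC2O", "c1ccccc1", 12L),
    list("NC(=O)c1cccnc1", "[c][CX3](=O)[NH2]", 1L),
    list("CCC(C#N)(c1ccccc1)C(=O)OCC", "[CX3](=O)[C][CH2][CH3]", 1L),
    list("CCC(C#N)(c1ccccc1)C(=O)OCC", "[C,c][OX2][CH2][CH3]", 1L),
    list("CC12CC=C3c4ccc(O)cc4CCC3C1CCC2(O)CC#N", "[OX2H]", 2L),
    list("CC12CCC3c4ccc(O)cc4CCC3C1CCC2O", "[CH3]", 1L),
    list("O", "[OX2H2]", 1L))
  for (cs in cases) {
    n <- length(match_pattern(parse_structure(cs[[1]]), cs[[2]]))
    expect_equal(n, cs[[3]], info = paste(cs[[1]], cs[[2]]))
  }
})

test_that("the steroid methyl-shift trigger finds the C/D-ring substructure", {
  # dehydrated protonated estradiol: 6-membered C ring + 5-membered D ring
  # carrying the C-17 cation, i.e. the six-ring trigger variant
  e2 <- apply_rule(oh17_protomer("1"), builtin_registry()$water_loss)[[1]]$ion
  maps <- match_pattern(e2$graph, "[CH3]C12CCCCC1CC[C+]2")
  expect_gte(length(maps), 1)
  m <- maps[[1]]
  expect_equal(e2$graph$atoms$hcount[m[1]], 3)       # methyl
  expect_equal(e2$graph$atoms$charge[m[10]], 1)      # carbocation
  # neither trigger matches the neutral molecule (no carbocation)
  expect_length(match_pattern(fixture_graph("1"), "[CH3]C12CCCCC1CC[C+]2"), 0)
  expect_length(match_pattern(fixture_graph("1"), "[CH3]C12CCCC1CC[C+]2"), 0)
})

test_that("matching is deterministic and mappings are sorted", {
  g <- fixture_graph("1")
  m1 <- match_pattern(g, "c1ccccc1")
  m2 <- match_pattern(g, "c1ccccc1")
  expect_identical(m1, m2)
  keys <- vapply(m1, function(m) paste(sprintf("%06d", m), collapse = ","), "")
  expect_identical(keys, sort(keys))
})

test_that("invalid SMARTS raises a pattern error", {
  expect_error(parse_smarts("[Q]"), class = "cidfrag_smarts_error")
  expect_error(parse_smarts("C)C"), class = "cidfrag_smarts_error")
  expect_error(parse_smarts("[CH3"), class = "cidfrag_smarts_error")
  expect_error(parse_smarts("C$C"), class = "cidfrag_smarts_error")
})

test_that("bond primitives constrain order, aromaticity and ring membership", {
  # '=' requires a true double bond
  expect_length(match_pattern(parse_structure("C=C"), "C=C"), 2)
  expect_length(match_pattern(parse_structure("CC"), "C=C"), 0)
  # kekulized aromatic bonds are not matched by '=' or '-'
  expect_length(match_pattern(parse_structure("c1ccccc1"), "C=C"), 0)
  # '!@' excludes ring bonds, '@' requires them
  expect_length(match_pattern(parse_structure("C1CCCCC1"), "[C]-!@[C]"), 0)
  expect_length(match_pattern(parse_structure("CC"), "[C]-!@[C]"), 2)
  expect_length(match_pattern(parse_structure("C1CCCCC1"), "[C]-@[C]"), 12)
})

test_that("disconnected patterns combine components disjointly", {
  # protonated hydroxyl plus a nitrile in the same molecule
  g <- parse_structure("N#CCCC[OH2+]")
  maps <- match_pattern(g, "[OH2+].[NX1]#C")
  expect_length(maps, 1)
  expect_equal(g$atoms$element[maps[[1]][1]], "O")
  expect_equal(g$atoms$element[maps[[1]][2]], "N")
  # no match when the acceptor is absent
  expect_length(match_pattern(parse_structure("CCC[OH2+]"), "[OH2+].[NX1]#C"), 0)
})
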