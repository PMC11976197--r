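test_that("SMILES parsing assigns implicit hydrogens and formulas", {
  w <- parse_structure("O")
  expect_equal(nrow(w$atoms), 1)
  expect_equal(w$atoms$hcount, 2)
  expect_formula(w, "H2O")

  expect_formula(fixture_graph("1"), "C18H24O2")
  expect_formula(parse_structure("NC(=O)c1cccnc1"), "C6H6N2O")
  expect_formula(parse_structure("CC12CCC3c4ccc(O)cc4CCC3C1CC[C+]2"),
                 "C18H23O+")
})

test_that("malformed SMILES raises a structured parse error", {
  expect_error(parse_structure("C("), class = "cidfrag_parse_error")
  expect_error(parse_structure("C1CC"), class = "cidfrag_parse_error")
  expect_error(parse_structure(""), class = "cidfrag_parse_error")
  expect_error(parse_structure("[CH3"), class = "cidfrag_parse_error")
})

test_that("formula and canonical key are invariant under atom reordering", {
  variants <- c("CC12CCC3c4ccc(O)cc4CCC3C1CCC2O",
                "Oc1ccc2c(c1)CCC1C2CCC2(C1CCC2O)C")
  fs <- vapply(variants, function(s) format(formula_of(parse_structure(s))), "")
  expect_true(all(fs == "C18H24O2"))
  keys <- vapply(variants, function(s) canonical_key(parse_structure(s)), "")
  expect_length(unique(keys), 1)
  # explicit atom-index permutations of the same graph
  g <- fixture_graph("3")
  set.seed(42)
  for (r in 1:5) {
    perm <- sample(nrow(g$atoms))
    inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
    b <- g$bonds
    b$a1 <- inv[b$a1]; b$a2 <- inv[b$a2]
    gp <- molgraph(g$atoms[perm, , drop = FALSE], b)
    expect_identical(canonical_key(gp), canonical_key(g))
    expect_identical(format(formula_of(gp)), format(formula_of(g)))
  }
})

test_that("canonical key distinguishes charge and radical state", {
  neutral <- parse_structure("CC12CCCC1CCC2")
  cation <- parse_structure("CC12CCCC1CC[C+]2")
  expect_false(canonical_key(neutral) == canonical_key(cation))
  rad <- cation
  rad$atoms$nrad[1] <- 1L
  rad$atoms$hcount[1] <- rad$atoms$hcount[1] - 1L
  expect_false(canonical_key(rad) == canonical_key(cation))
})

test_that("monoisotopic m/z follows the no-electron-correction convention", {
  printed <- c("C11H11O+" = 159.08, "C19H21O+" = 265.16, "C10H9O+" = 145.07,
               "C18H25O2+" = 273.19, "C18H23O+" = 255.17,
               "C17H20O+." = 240.15, "C20H24NO2+" = 310.18,
               "C20H22NO+" = 292.17, "C13H16NO2+" = 218.12,
               "C11H12NO2+" = 190.09, "C9H8NO2+" = 162.06,
               "C6H7N2O+" = 123.06)
  for (f in names(printed)) {
    expect_equal(round(monoisotopic_mz(parse_formula(f)), 2), printed[[f]],
                 info = f)
  }
  expect_equal(monoisotopic_mz(parse_formula("H2O")), 18.0105646, tolerance = 1e-6)
  expect_equal(monoisotopic_mz(elemental_formula(integer(0))), 0)
  expect_error(monoisotopic_mz(elemental_formula(c(Xx = 1L))),
               class = "cidfrag_element_error")
})

test_that("monoisotopic mass is additive over disjoint parts", {
  parts <- list("C6H6", "H2O", "C2H4", "CHN")
  for (i in 1:3) {
    a <- parse_formula(parts[[i]]); b <- parse_formula(parts[[i + 1]])
    ab <- sum_formulas(list(a, b))
    expect_equal(monoisotopic_mz(ab), monoisotopic_mz(a) + monoisotopic_mz(b),
                 tolerance = 1e-9)
  }
})

test_that("aromaticity perception is stable on reference structures", {
  benz <- parse_structure("c1ccccc1")
  expect_true(all(benz$atoms$aromatic))
  expect_true(all(benz$bonds$aromatic))
  pyr <- parse_structure("c1ccncc1")
  expect_true(all(pyr$atoms$aromatic))
  chx <- parse_structure("C1CC=CCC1")
  expect_false(any(chx$atoms$aromatic))
  est <- fixture_graph("1")
  expect_equal(sum(est$atoms$aromatic), 6)    # A ring only
  qrc <- fixture_graph("6")
  expect_equal(sum(qrc$atoms$aromatic), 12)   # two benzene rings; pyranone not
})

test_that("valence validation rejects impossible atoms", {
  bad <- molgraph(
    data.frame(element = c("C", "O"), charge = 0L, nrad = 0L,
               hcount = c(4L, 2L), aromatic = FALSE),
    data.frame(a1 = 1L, a2 = 2L, order = 1L, aromatic = FALSE),
    validate = FALSE)
  expect_error(validate_molgraph(bad), class = "cidfrag_valence_error")
  expect_false(validate_molgraph(bad, quiet = TRUE))
})

test_that("graph components split and reperceive", {
  g <- parse_structure("CCO.c1ccccc1")
  parts <- graph_components(g)
  expect_length(parts, 2)
  fs <- sort(vapply(parts, function(p) format(formula_of(p)), ""))
  expect_identical(fs, c("C2H6O", "C6H6"))
})
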