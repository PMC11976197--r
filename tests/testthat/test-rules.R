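test_that("the built-in registry passes static validation", {
  reg <- builtin_registry()
  expect_gte(length(reg), 11)
  expect_true(all(c("methyl_shift", "water_loss", "proton_transfer",
                    "hydride_shift", "ring_opening", "retro_diels_alder",
                    "mclafferty", "alk_o_cleavage", "hcn_loss", "allyl_shift",
                    "methyl_radical_loss") %in% names(reg)))
  diag <- validate_rules(reg)
  expect_equal(nrow(diag), 0)
  expect_identical(reg$methyl_shift$triggers,
                   c("[CH3]C12CCCC1CC[C+]2", "[CH3]C12CCCCC1CC[C+]2"))
  expect_equal(length(apply_rule(
    ion_species(parse_structure("CC(C)[OH2+]")),
    reg$water_loss)[[1]]$neutrals), 1)
})

test_that("the methyl shift executes its four steps on a toy cation", {
  toy <- ion_species(parse_structure("CC12CCCC1CC[C+]2"))
  maps <- match_pattern(toy$graph, "[CH3]C12CCCC1CC[C+]2")
  shifted <- apply_methyl_shift(toy, maps[[1]])
  # formula and m/z unchanged; charge moved to the former methyl-bearing
  # ring-fusion carbon, now a tertiary carbocation
  expect_identical(format(shifted$formula), format(toy$formula))
  expect_equal(shifted$mz, toy$mz)
  old_c1 <- maps[[1]][2]; old_cp <- maps[[1]][9]
  expect_equal(shifted$graph$atoms$charge[old_c1], 1)
  expect_equal(shifted$graph$atoms$charge[old_cp], 0)
  # independently derived product: methyl bonded to the formerly charged atom
  expected <- parse_structure("CC1CCC2(CCC[C+]12)")
  expect_identical(shifted$key, canonical_key(expected))
  # replaying the inverse edit script restores the original species
  inv <- list(graph_edit("CLEAVE_BOND", "me", "cp"),
              graph_edit("FORM_BOND", "me", "c1", order = 1),
              graph_edit("DEC_CHARGE", "c1"),
              graph_edit("INC_CHARGE", "cp"))
  back <- cidfrag:::execute_edits(shifted$graph, inv,
                                  c(me = 1L, c1 = 2L, cp = 9L), maps[[1]])
  expect_identical(canonical_key(back$graph), toy$key)
})

test_that("methyl shift preconditions and non-matching substrates", {
  acyclic <- ion_species(parse_structure("CC[C+]C"))
  expect_length(apply_rule(acyclic, builtin_registry()$methyl_shift), 0)
  toy <- ion_species(parse_structure("CC12CCCC1CC[C+]2"))
  expect_error(apply_methyl_shift(toy, stats::setNames(1:9, 1:9) * 0L + 2L),
               class = "cidfrag_precondition_error")
})

test_that("water and HCN losses reproduce the steroid pathway steps", {
  d1 <- oh17_protomer("3")
  expect_equal(round(d1$mz, 2), 310.18)
  apps <- apply_rule(d1, builtin_registry()$water_loss)
  expect_gte(length(apps), 1)
  d2 <- apps[[1]]$ion
  expect_identical(format(d2$formula), "C20H22NO+")
  expect_identical(format(formula_of(apps[[1]]$neutrals[[1]])), "H2O")
  hcn <- apply_rule(d2, builtin_registry()$hcn_loss)
  expect_gte(length(hcn), 1)
  expect_identical(format(hcn[[1]]$ion$formula), "C19H21O+")
  expect_identical(format(formula_of(hcn[[1]]$neutrals[[1]])), "CHN")
})

test_that("every rule conserves atoms and charge on every fixture protomer", {
  reg <- builtin_registry()
  for (lab in fixture_compounds()$label) {
    for (ion in ionize(fixture_graph(lab))) {
      for (rule in reg) {
        for (app in apply_rule(ion, rule)) {
          total <- cidfrag:::sum_formulas(
            c(list(app$ion$formula), lapply(app$neutrals, formula_of)))
          expect_identical(total$counts, ion$formula$counts,
                           info = paste(lab, rule$id))
          expect_equal(total$charge, 1L, info = paste(lab, rule$id))
          # rearrangements preserve m/z; cleavages strictly decrease it
          if (app$is_cleavage) {
            expect_gt(app$delta_mz, 1e-6, label = paste(lab, rule$id))
          } else {
            expect_lt(abs(app$delta_mz), 1e-9, label = paste(lab, rule$id))
          }
        }
      }
    }
  }
})

test_that("rule registries round-trip through the YAML rules file", {
  reg <- builtin_registry()
  path <- withr::local_tempfile(fileext = ".yml")
  write_rules(reg, path)
  back <- read_rules(path)
  expect_identical(names(back), names(reg))
  for (id in names(reg)) {
    expect_identical(back[[id]]$triggers, reg[[id]]$triggers, info = id)
    expect_identical(vapply(back[[id]]$edits, function(e) e$opcode, ""),
                     vapply(reg[[id]]$edits, function(e) e$opcode, ""),
                     info = id)
  }
  expect_equal(nrow(validate_rules(back)), 0)
})

test_that("validation flags unbalanced charge edits and unresolved labels", {
  bad <- frag_rule("bad_charge", "rearrangement", triggers = "[C+]C",
                   labels = list(c(a = 1L, b = 2L)),
                   edits = list(graph_edit("INC_CHARGE", "b")))
  diag <- validate_rules(list(bad))
  expect_true(any(diag$rule == "bad_charge" & diag$check == "charge_balance"))
  bad2 <- frag_rule("bad_label", "rearrangement", triggers = "CC",
                    labels = list(c(a = 1L)),
                    edits = list(graph_edit("MOVE_H", "a", "zz")))
  expect_true(any(validate_rules(list(bad2))$check == "labels"))
})

test_that("repeated application yields identical product sets", {
  ion <- oh17_protomer("1")
  reg <- builtin_registry()
  a1 <- apply_rule(ion, reg$water_loss)
  a2 <- apply_rule(ion, reg$water_loss)
  expect_identical(vapply(a1, function(a) a$ion$key, ""),
                   vapply(a2, function(a) a$ion$key, ""))
})
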