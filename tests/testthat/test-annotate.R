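# small helper: hand-built tree table for tolerance tests
toy_tree <- function(mz, roots = 1L) {
  structure(list(
    nodes = tibble::tibble(id = seq_along(mz), key = as.character(seq_along(mz)),
                           formula = paste0("X", seq_along(mz)), mz = mz,
                           charge = 1L, radical = FALSE, hof = 0,
                           stage = c(0L, rep(1L, length(mz) - 1))),
    edges = tibble::tibble(parent = integer(0), child = integer(0),
                           rule = character(0), neutrals = character(0),
                           delta_mz = numeric(0), enthalpy = numeric(0)),
    roots = roots, ions = NULL, config = engine_config(),
    config_hash = "toy"), class = "frag_tree")
}

test_that("two-column text peak lists parse, sort and normalize", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# ESI-MS2 of the butanoate ester", "218 47", "190 100", "162 10"), f)
  sp <- read_peaklist(f)
  expect_equal(nrow(sp), 3)
  expect_identical(sp$mz, c(162, 190, 218))   # sorted
  expect_equal(max(sp$intensity), 100)

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines("# nothing", empty)
  expect_error(read_peaklist(empty), class = "cidfrag_format_error")

  neg <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("100 5", "110 -3"), neg)
  expect_error(read_peaklist(neg), class = "cidfrag_format_error")

  dup <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("100 5", "100 7"), dup)
  expect_error(read_peaklist(dup), class = "cidfrag_format_error")
})

test_that("MGF and MSP records parse with intensity normalization", {
  mgf <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=demo", "PEPMASS=218.12", "CHARGE=1+",
               "162 100", "190 1000", "218 470", "END IONS"), mgf)
  sp <- read_peaklist(mgf)
  expect_equal(sp$intensity, c(10, 100, 47))
  expect_identical(attr(sp, "label"), "demo")

  msp <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: demo msp", "PrecursorMZ: 123.06", "Num Peaks: 3",
               "53 25; 78 50; 80 100"), msp)
  sp2 <- read_peaklist(msp)
  expect_equal(nrow(sp2), 3)
  expect_equal(sp2$intensity[sp2$mz == 80], 100)
  expect_identical(attr(sp2, "label"), "demo msp")
})

test_that("intensity filtering fixes the absolute-score denominator", {
  expect_equal(nrow(filter_peaks(builtin_spectrum("3"), 5)), 8)
  expect_equal(nrow(filter_peaks(builtin_spectrum("2"), 5)), 16)
  expect_equal(nrow(filter_peaks(builtin_spectrum("4"), 10)), 3)
  sp <- builtin_spectrum("2")
  expect_equal(nrow(filter_peaks(sp, 0)), nrow(sp))      # identity
  # raising the threshold never increases N
  Ns <- vapply(c(0, 5, 10, 20, 40), function(t) nrow(filter_peaks(sp, t)), 0L)
  expect_true(all(diff(Ns) <= 0))
})

test_that("peak matching respects the tolerance and the precursor matches", {
  tr <- toy_tree(c(310.18, 159.081))
  sp <- ms_spectrum(c(159, 310), c(35, 100))
  ann5 <- annotate(tr, sp, tolerance = 0.5)
  expect_true(all(ann5$peaks$annotated))
  ann05 <- annotate(tr, sp, tolerance = 0.05)
  expect_false(ann05$peaks$annotated[ann05$peaks$mz == 159])
  # the precursor ion (root) is matchable, and can be excluded for
  # comparator-style scoring
  tree5 <- fixture_tree("5")
  a_in <- annotate(tree5, builtin_spectrum("5"), threshold = 5)
  expect_true(a_in$peaks$annotated[a_in$peaks$mz == 123])
  a_ex <- annotate(tree5, builtin_spectrum("5"), threshold = 5,
                   include_precursor = FALSE)
  expect_false(a_ex$peaks$annotated[a_ex$peaks$mz == 123])
  # empty tree annotates nothing
  empty <- toy_tree(1000)
  empty$nodes <- empty$nodes[0, ]
  a0 <- annotate(empty, sp, tolerance = 0.5)
  expect_false(any(a0$peaks$annotated))
})

test_that("ambiguous matches rank by mass error then stability", {
  tr <- toy_tree(c(200, 159.2, 159.05))
  tr$nodes$hof <- c(0, -5, -1)
  ann <- annotate(tr, ms_spectrum(159.1, 100), tolerance = 0.5)
  expect_equal(nrow(ann$matches), 2)
  expect_equal(ann$matches$ion[1], 3L)  # |dmz| 0.05 beats 0.1
})

test_that("weighted and absolute scores follow the intensity sums", {
  a4 <- annotate(fixture_tree("4"), builtin_spectrum("4"), threshold = 10)
  w <- weighted_score(a4); ab <- absolute_score(a4)
  expect_equal(w[["s_max"]], 157)
  expect_equal(w[["s"]], 157)            # all three peaks annotated
  expect_equal(ab, c(n = 3L, N = 3L))
  a5 <- annotate(fixture_tree("5"), builtin_spectrum("5"), threshold = 5)
  expect_equal(weighted_score(a5), c(s = 195, s_max = 195))
  expect_equal(absolute_score(a5), c(n = 5L, N = 5L))
  # no annotation: s = 0, n = 0, N intact
  far <- annotate(toy_tree(1000), builtin_spectrum("4"), threshold = 10)
  expect_equal(weighted_score(far)[["s"]], 0)
  expect_equal(absolute_score(far), c(n = 0L, N = 3L))
})

test_that("score bounds and the s = s_max equivalence hold", {
  anns <- list(
    annotate(fixture_tree("4"), builtin_spectrum("4"), threshold = 10),
    annotate(fixture_tree("3"), builtin_spectrum("3"), threshold = 5),
    annotate(fixture_tree("5"), builtin_spectrum("5"), threshold = 5),
    annotate(toy_tree(1000), builtin_spectrum("4"), threshold = 10))
  for (a in anns) {
    w <- weighted_score(a); ab <- absolute_score(a)
    expect_gte(w[["s"]], 0); expect_lte(w[["s"]], w[["s_max"]])
    expect_gte(ab[["n"]], 0); expect_lte(ab[["n"]], ab[["N"]])
    expect_equal(w[["s"]] == w[["s_max"]], ab[["n"]] == ab[["N"]])
  }
})

test_that("scores are invariant under peak permutation", {
  sp <- builtin_spectrum("3")
  perm <- sample(seq_len(nrow(sp)))
  sp2 <- ms_spectrum(sp$mz[perm], sp$intensity[perm], label = "3",
                     mass_range = attr(sp, "mass_range"))
  tr <- fixture_tree("3")
  expect_equal(weighted_score(annotate(tr, sp2, threshold = 5)),
               weighted_score(annotate(tr, sp, threshold = 5)))
})

test_that("the weighted score agrees with a brute-force indicator sum", {
  # independent oracle: plain double loop over peaks x tree ions
  for (lab in c("3", "4", "5")) {
    tr <- fixture_tree(lab)
    thr <- fixture_compounds()$threshold[fixture_compounds()$label == lab]
    sp <- filter_peaks(builtin_spectrum(lab), thr)
    s_oracle <- 0
    for (i in seq_len(nrow(sp))) {
      hit <- FALSE
      for (m in tr$nodes$mz) if (abs(m - sp$mz[i]) <= 0.5) hit <- TRUE
      if (hit) s_oracle <- s_oracle + sp$intensity[i]
    }
    a <- annotate(tr, sp, tolerance = 0.5)
    expect_equal(weighted_score(a)[["s"]], s_oracle, info = lab)
  }
})

test_that("reports carry the determined/maximum score string and round-trip", {
  a3 <- annotate(fixture_tree("3"), builtin_spectrum("3"), threshold = 5)
  lines <- report(a3)
  expect_true(any(grepl("/343 (", lines, fixed = TRUE)))
  expect_equal(sum(grepl("^\\s+[0-9]+\\.[0-9]+\\s", lines)), 8)
  far <- annotate(toy_tree(1000), builtin_spectrum("4"), threshold = 10)
  expect_true(any(grepl("score: 0/", report(far), fixed = TRUE)))
  path <- withr::local_tempfile(fileext = ".json")
  report(a3, path = path)
  back <- read_report_json(path)
  expect_equal(back$weighted$s, weighted_score(a3)[["s"]])
  expect_equal(nrow(back$peaks), 8)
  expect_identical(back$score, cidfrag:::score_string(a3))
})

test_that("peaks outside the acquisition mass range are not counted", {
  sp <- ms_spectrum(c(120, 200, 300), c(10, 100, 50), mass_range = c(150, 320))
  a <- annotate(toy_tree(c(200, 300)), sp, tolerance = 0.5)
  expect_equal(absolute_score(a)[["N"]], 2L)
  expect_equal(weighted_score(a)[["s_max"]], 150)
})
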