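# Packaged worked examples: compounds, their printed ESI(+)-MS2 peak lists
# and expected pathway ions, plus a synthetic-spectrum generator so every
# module is testable offline.

#' Fixture compounds
#'
#' The worked ESI(+) compounds shipped with the package: 17beta-estradiol
#' ("1"), estriol 3-methyl ether ("2"), delta-9,11-dehydro-17alpha-
#' cyanomethylestradiol ("3"), 2-cyano-2-phenylbutanoic acid ethyl ester
#' ("4"), nicotinamide ("5") and quercetin ("6").  SMILES are transcribed
#' from the named structures (standard steroid/flavonoid connectivity); the
#' stored formula makes any transcription error fail loudly in tests.
#'
#' @return Tibble with columns label, name, smiles, formula, mz_mh
#'   (monoisotopic \[M+H\]+ m/z, 2 dp) and threshold (the relative-intensity
#'   cutoff used with the compound's spectrum).
#' @export
fixture_compounds <- function() {
  tibble(
    label = c("1", "2", "3", "4", "5", "6"),
    name = c("17beta-estradiol",
             "estriol 3-methyl ether",
             "delta-9,11-dehydro-17alpha-cyanomethylestradiol",
             "2-cyano-2-phenylbutanoic acid ethyl ester",
             "nicotinamide",
             "quercetin"),
    smiles = c(
      "CC12CCC3c4ccc(O)cc4CCC3C1CCC2O",
      "COc1ccc2c(c1)CCC1C2CCC2(C)C1CC(O)C2O",
      "CC12CC=C3c4ccc(O)cc4CCC3C1CCC2(O)CC#N",
      "CCC(C#N)(c1ccccc1)C(=O)OCC",
      "NC(=O)c1cccnc1",
      "O=C1c2c(O)cc(O)cc2OC(c2ccc(O)c(O)c2)=C1O"),
    formula = c("C18H24O2", "C19H26O3", "C20H23NO2", "C13H15NO2",
                "C6H6N2O", "C15H10O7"),
    mz_mh = c(273.19, 303.20, 310.18, 218.12, 123.06, 303.05),
    threshold = c(5, 5, 5, 10, 5, 10))
}

#' Expected pathway ions of the worked fragmentation schemes
#'
#' Ion compositions and printed 2-decimal m/z values of the documented
#' pathways for compounds 1 (E-series), 3 (D-series) and 4 (P-series).
#'
#' @return Tibble: compound label, ion label, formula, radical flag, mz.
#' @export
fixture_pathway_ions <- function() {
  tibble(
    compound = c("1", "1", "1", "1", "1",
                 "3", "3", "3", "3", "3", "3",
                 "4", "4", "4"),
    ion = c("E1", "E2", "E3/E4", "E5", "E6",
            "D1", "D2", "D3", "D5", "D7", "D8",
            "P1", "P3/P4/P6", "P5/P7"),
    formula = c("C18H25O2+", "C18H23O+", "C18H23O+", "C11H11O+", "C17H20O+.",
                "C20H24NO2+", "C20H22NO+", "C19H21O+", "C10H9O+", "C11H9O+",
                "C11H11O+",
                "C13H16NO2+", "C11H12NO2+", "C9H8NO2+"),
    mz = c(273.19, 255.17, 255.17, 159.08, 240.15,
           310.18, 292.17, 265.16, 145.07, 157.06, 159.08,
           218.12, 190.09, 162.06))
}

#' Built-in experimental spectra
#'
#' Printed ESI(+)-MS2 peak lists of the worked compounds: estriol 3-methyl
#' ether ("2", 16 peaks, mass range 100-320), the 9,11-dehydro
#' cyanomethylestradiol ("3", 8 peaks, 150-320), the cyanophenylbutanoate
#' ester ("4", 3 peaks, 60-220) and nicotinamide ("5", 5 peaks).  Quercetin
#' ("6") ships as an m/z list with uniform placeholder intensities (the
#' source reports m/z only), and is therefore excluded from weighted-score
#' fixtures.
#'
#' @param label compound label ("2".."6").
#' @return An `ms_spectrum`.
#' @export
builtin_spectrum <- function(label) {
  man <- spectrum_manifest()
  row <- man[man$label == as.character(label), , drop = FALSE]
  if (nrow(row) != 1) {
    abort(paste0("no built-in spectrum for label '", label, "'"),
          class = "cidfrag_fixture_error")
  }
  path <- system.file("extdata", "spectra", row$file, package = "cidfrag")
  read_peaklist(path, format = "txt", label = as.character(label),
                ms_stage = row$ms_stage,
                mass_range = as.numeric(c(row$range_lo, row$range_hi)))
}

#' Manifest of the packaged peak-list files
#'
#' @return Tibble: compound label, file name (under
#'   `inst/extdata/spectra/`), MS stage, evaluation threshold (%) and
#'   acquisition mass range.
#' @export
spectrum_manifest <- function() {
  path <- system.file("extdata", "spectra", "manifest.csv", package = "cidfrag")
  as_tibble(utils::read.csv(path, comment.char = "#",
                            colClasses = c(label = "character")))
}

#' Generate a synthetic spectrum from a fragmentation tree
#'
#' Samples `n_peaks` tree-node m/z values, assigns log-normal intensities
#' normalized to a 100% base peak, and optionally adds decoy peaks at
#' non-tree m/z values and Gaussian m/z jitter.  Deterministic under a fixed
#' seed.
#'
#' @param tree a `frag_tree`.
#' @param n_peaks number of true peaks to sample (capped at the number of
#'   distinct tree m/z values).
#' @param decoy_fraction fraction of additional decoy peaks (relative to
#'   `n_peaks`) placed at least `decoy_min_dist` from any tree ion.
#' @param jitter_sd Gaussian m/z jitter standard deviation (Th).
#' @param seed RNG seed.
#' @param decoy_min_dist minimum distance of decoys from any tree m/z.
#' @return An `ms_spectrum`.
#' @export
synth_spectrum <- function(tree, n_peaks = 10, decoy_fraction = 0,
                           jitter_sd = 0, seed = 1L, decoy_min_dist = 1.0) {
  mzs <- sort(unique(round(tree$nodes$mz, 6)))
  if (length(mzs) == 0) {
    abort("tree has no ions to sample", class = "cidfrag_fixture_error")
  }
  n_peaks <- min(n_peaks, length(mzs))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    mz <- sort(sample(mzs, n_peaks))
    if (jitter_sd > 0) mz <- mz + stats::rnorm(n_peaks, 0, jitter_sd)
    it <- stats::rlnorm(n_peaks, meanlog = 3, sdlog = 1)
    n_decoy <- round(decoy_fraction * n_peaks)
    if (n_decoy > 0) {
      lo <- min(mzs) * 0.3; hi <- max(mzs) * 1.1
      dec <- numeric(0)
      tries <- 0
      while (length(dec) < n_decoy && tries < 1000) {
        cand <- stats::runif(1, lo, hi)
        if (min(abs(cand - mzs)) >= decoy_min_dist) dec <- c(dec, cand)
        tries <- tries + 1
      }
      mz <- c(mz, dec)
      it <- c(it, stats::rlnorm(length(dec), meanlog = 2, sdlog = 1))
    }
    ms_spectrum(mz, 100 * it / max(it), label = "synthetic")
  })
}
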