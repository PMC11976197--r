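Package: cidfrag
Title: Rule-Based In Silico Fragmentation and Annotation of ESI(+) Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An in silico fragmentation engine for positive-mode electrospray
    (ESI(+)) collision-induced dissociation spectra of small molecules.
    Candidate structures given as SMILES are protonated, fragment ions are
    generated by SMARTS-triggered cleavage and rearrangement rules (methyl
    shift, McLafferty-type alkene eliminations, retro-Diels-Alder, water/HCN/
    CO/NH3 losses, hydride and allyl shifts, homolytic methyl-radical loss)
    together with weak-bond heterolysis, and chemically plausible ions are
    selected by surrogate reaction enthalpies.  The resulting fragmentation
    tree is matched against experimental peak lists (two-column text, MGF,
    MSP) and annotations are summarised with intensity-weighted and absolute
    scores.  An interface to an external semiempirical program (MOPAC/PM7)
    is provided for heats of formation and bond orders; a deterministic
    heuristic evaluator is the default backend.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
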