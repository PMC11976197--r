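# cidfrag

Rule-based in silico fragmentation and annotation of ESI(+) tandem mass
spectra.

## The problem

Collision-induced dissociation (CID) spectra of small molecules — steroids,
flavonoids, pesticides, drug-like compounds — are still interpreted largely
by hand: an expert proposes a protonation site, walks the ion through
carbocation chemistry (hydride and methyl shifts, ring openings, water/HCN/CO
losses, McLafferty-type eliminations, retro-Diels–Alder cleavages), and
assigns each spectral peak to a fragment ion. `cidfrag` automates this
workflow for positive-mode electrospray ([M+H]⁺) spectra while keeping every
step chemically explicit:

1. **Ionization** — one protomer per basic heteroatom site of the input
   SMILES.
2. **Rule-based expansion** — SMARTS-triggered cleavage and rearrangement
   rules (a declarative registry with a closed graph-edit vocabulary:
   `CLEAVE_BOND`, `FORM_BOND`, `MOVE_H`, charge and radical edits), plus
   heterolysis of weak bonds identified from computed bond orders. Every
   application conserves atoms and charge, and users can extend the registry
   from a YAML rules file.
3. **Stability-guided selection** — candidate ions are ranked by reaction
   enthalpy ΔH = Σ ΔHf(products) − ΔHf(precursor) and kept within a
   configurable window. Heats of formation and bond orders come from a
   deterministic additive surrogate (default) or from an external
   semiempirical program (MOPAC/PM7, opt-in).
4. **Fragmentation tree** — a DAG from the protomer roots to all retained
   ions, with the applied rule and neutral loss on every edge, serializable
   to JSON and DOT.
5. **Annotation and scoring** — experimental peak lists (two-column text,
   MGF, MSP) are matched against tree ions within a tolerance (±0.5 Th
   default for unit-resolution ion traps; ppm mode for high-resolution
   data). Two scores summarize a spectrum: the **weighted score**
   `s = Σ_{f ∈ F} intensity_f` over the annotated peak set `F` (with maximum
   `s_max` over all peaks above the intensity threshold) and the **absolute
   score** `n/N`, the number of annotated peaks out of all retained peaks.

## Worked example

Nicotinamide (C₆H₆N₂O, [M+H]⁺ at m/z 123.06) against its printed ESI(+)-MS²
peak list:

```r
library(cidfrag)

tree <- fragment("NC(=O)c1cccnc1")
glance(tree)
#>   n_ions n_edges n_roots max_stage precursor_mz
#> 1      9       6       3         2         123.

ann <- annotate(tree, builtin_spectrum("5"), tolerance = 0.5, threshold = 5)
writeLines(report(ann))
#> compound: 5
#> tolerance: 0.5 Th; intensity threshold: 5%
#> score: 195/195 (5/5)
#>
#>    53.00    25%  C4H5+ (m/z 53.0391)  hnco_loss (-CHNO) > azine_hcn_loss (-CHN)
#>    78.00    50%  C5H4N+ (m/z 78.0344)  nh3_loss (-H3N) > co_loss (-CO)
#>    80.00   100%  C5H6N+ (m/z 80.0500)  hnco_loss (-CHNO)
#>   106.00     5%  C6H4NO+ (m/z 106.0293)  nh3_loss (-H3N)
#>   123.00    15%  C6H7N2O+ (m/z 123.0558)
```

All five peaks are explained: the protonated molecule, NH₃ loss to the
acylium ion (m/z 106), its CO loss (m/z 78), HNCO loss to protonated
pyridine (m/z 80) and the ring HCN loss to C₄H₅⁺ (m/z 53) — giving the
weighted score 195/195 and absolute score 5/5. `tidy(tree)` returns the ion
table, `autoplot(ann)` draws the annotated stick spectrum, and
`write_tree_json()` / `write_tree_dot()` export the tree.

Six worked compounds ship with the package (`fixture_compounds()`,
`builtin_spectrum()`): 17β-estradiol, estriol 3-methyl ether, a
9,11-dehydro-17α-cyanomethyl estradiol, 2-cyano-2-phenylbutanoic acid ethyl
ester, nicotinamide and quercetin, together with their printed MS² peak
lists and documented pathway ions (`fixture_pathway_ions()`).

A thin command-line interface is installed at
`system.file("cli", "cidfrag", package = "cidfrag")` with subcommands
`fragment`, `annotate`, `score`, `validate-rules` and `fixtures`.

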