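---
title: "The cidfrag fragmentation engine: model, rules and selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cidfrag fragmentation engine: model, rules and selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidfrag)
```

## The model

`cidfrag` simulates collision-induced dissociation of protonated small
molecules in positive-mode electrospray. The underlying picture is classical
even-electron ion chemistry: after protonation at a heteroatom lone pair,
the ion isomerizes and dissociates through a small vocabulary of elementary
steps — heterolytic bond cleavages assisted by the charge, hydride and alkyl
shifts toward more stable carbocations, concerted eliminations (McLafferty,
retro-Diels–Alder, retro-ene), and occasional homolysis to distonic
radical cations. Which of the combinatorially many steps actually occur is
decided thermodynamically: steps whose reaction enthalpy is close to the
most favorable channel of the same precursor are retained.

The engine therefore consists of three orthogonal parts:

* a **molecular graph** layer (atoms with formal charge, radical count and
  implicit hydrogens; kekulized bonds with a derived aromaticity flag),
* a **rule registry** (SMARTS-subset triggers plus ordered graph-edit
  scripts over a closed opcode set), and
* a **stability evaluator** returning heats of formation and bond orders.

### Assumptions

* Singly charged, even-electron precursors ([M+H]⁺); the only odd-electron
  species are distonic radical cations formed by explicit homolysis rules.
* Constitution-level chemistry: stereochemistry is ignored, as the rules
  operate on connectivity only.
* Protonation at N, O and S lone pairs; π-protonation of carbon is excluded
  by default (ring protonation still arises indirectly through H-moving
  rules).
* Collision energy is not modeled; the engine predicts which ions can form,
  not their intensities.

## Fragmentation rules

`builtin_registry()` ships sixteen rules: the steroid C/D-ring methyl shift
(two trigger patterns; a 1,2-Wagner–Meerwein migration executed as
four explicit edits), water elimination from protonated hydroxyls, proton
transfers between heteroatoms (including to nitrile and azine nitrogen),
1,2-hydride shifts, allylic 1,3 charge shifts, ring opening and acyclic
β-scission at carbocations, retro-Diels–Alder cleavage of cyclohexenes,
McLafferty-type alkene elimination on the acid side of esters, Alk–O
cleavage/alcohol-side alkene elimination of ethyl esters, HCN loss from
nitriles α to a carbocation, HCN loss from protonated azine rings, NH₃ and
HNCO losses of amides, CO loss from acylium ions, and homolytic
methyl-radical loss.

Rules are data, not code. Each rule lists its triggers, a per-trigger label
map, and an edit script drawn from `CLEAVE_BOND`, `FORM_BOND` (which also
sets the order of an existing bond), `MOVE_H` (proton or hydride, flagged),
`INC_CHARGE`/`DEC_CHARGE`, `SET_RADICAL` and `SPLIT_COMPONENTS`. The
executor verifies valence validity, atom conservation and charge
conservation on every application and raises a structured error — naming the
rule and embedding — rather than skipping a failing script. Registries
round-trip through a YAML rules file (`write_rules()`/`read_rules()`), and
`validate_rules()` performs the same checks statically (opcode and label
resolution, balanced charge edits) and dynamically on fixture ions. The
shipped set covers the chemistry exercised by the packaged compounds; the
published engines in this field carry larger inventories, and the rules file
is the intended extension point.

### The trigger dialect

Triggers are written in a documented SMARTS subset: organic-subset element
symbols (lower case aromatic), bracket atoms with element alternatives and
`H`/`X`/charge primitives, bond symbols `- = # : ~` with ring qualifiers
`@`/`!@`, branches, ring closures, and `.` for disconnected components.
Bond orders refer to the kekulized graph. Matching is exact subgraph
monomorphism (igraph's LAD solver over per-atom candidate domains, with a
bond-constraint post-filter); all embeddings are enumerated in a
deterministic sorted order, automorphic images counting separately, as in
standard SMARTS semantics.

One observation worth recording: of the two shipped methyl-shift triggers,
`[CH3]C12CCCC1CC[C+]2` encodes a 5-5-fused ring pair, while the estradiol
C/D system (six-membered C ring, five-membered D ring, cation at C-17) is
matched by the second, six-ring variant `[CH3]C12CCCCC1CC[C+]2`. The engine
always tries both.

## The stability surrogate

The default evaluator is a deterministic additive model, not a quantum
chemical method: heats of formation are sums of atom terms, bond terms
(single −70, double −120, triple −165, aromatic −85 kcal/mol), a charge-site
penalty, a radical penalty, and a stabilization bonus for free small
closed-shell neutrals (≤ 2 heavy atoms −50, 3 heavy atoms −35 kcal/mol).
The charge-site penalty implements the textbook carbocation order —
heteroatom-stabilized (oxocarbenium/onium) < benzylic/allylic < tertiary <
secondary < primary ≪ methyl, with vinyl and aryl cations strongly
disfavored. Because atom terms cancel exactly in any atom-conserving
reaction, reaction enthalpies depend only on the bond, penalty and bonus
terms, and the evaluator's additive constant is immaterial.

The constants were calibrated once so that representative channels take
plausible relative enthalpies on a PM7-like scale — water loss from a
protonated hydroxyl ≈ +28 kcal/mol, nitrile-assisted HCN loss ≈ −34,
retro-Diels–Alder of a cyclohexene ≈ +40, benzylic methyl-radical homolysis
≈ +42, β-scissions ≈ +10…35, hydride/methyl shifts within ±15 — and then
frozen. The surrogate's purpose is ranking within the selection window, not
absolute thermochemistry: its errors are tolerable exactly because the
engine compares channels of the same precursor.

Bond orders are nominal orders minus fixed decrements for bonds α (0.20) and
β (0.15) to the charge site; aromatic bonds are pinned at 1.5 and never
flagged weak. `weak_bonds()` thresholds these orders (default 0.9), and the
engine attempts heterolysis of each weak bond in both charge-retention
directions, discarding any direction that leaves an invalid valence or a
negative formal charge.

An interface to an external semiempirical program (MOPAC, PM7) provides the
same contract — `evaluate(graph)` → heat of formation plus bond orders —
with deck generation from a seeded 3D embedding, output parsing, caching by
canonical key, and a large-penalty fallback (never a silent drop) for
non-converged runs. It is opt-in via `make_evaluator("external")`; all
shipped results use the heuristic backend.

## The engine loop and its parameters

`fragment()` is a staged breadth-first search. Level 0 is the protomer set.
Each stage then (a) takes the closure of the current pool under
mass-preserving steps — rearrangement rules and ring heterolyses — with any
one rearrangement rule applied at most `rearrangement_cap` (default 2) times
per root-to-leaf path and at most `max_rearrangement_rounds` (default 6)
closure iterations, and (b) collects all mass-losing cleavage applications
of the pool into the next level. Ions are deduplicated by a canonical key
(Weisfeiler–Lehman-refined atom invariants, BLISS canonical labeling,
readable serialization); an ion reached twice is merged with multiple parent
edges. Termination is guaranteed by the depth bound, the rearrangement caps
and the key-based deduplication.

Selection (`select_stable()`) is applied at every step:

* **Window** (default 30 kcal/mol): a candidate is kept if its reaction
  enthalpy lies within the window of the minimum among candidates of the
  *same precursor* (`window_scope = "parent"`). A global per-level minimum
  (`window_scope = "level"`) is available but makes selection depend on
  unrelated siblings: one ion's facile β-scission would veto another ion's
  only channel, although in CID each isolated precursor fragments
  independently. The per-parent scope is the package's design choice.
* **Isomer cap** (`max_isomers_per_formula`, default 12): at each cleavage
  selection, at most this many structural isomers of one ion composition are
  retained, most stable first. Annotation only sees compositions (m/z), so
  the level budget is better spent on composition diversity than on
  near-duplicate isomers.
* **Level cap** (`max_ions_per_level`, default 50), ordered by window excess,
  then absolute enthalpy, then canonical key — with the guarantee that every
  pool precursor keeps its single most favorable channel. Selection prunes
  channels within a precursor and redundant isomers; it never silences a
  precursor that was itself already selected as chemically meaningful.

Two further defaults: `max_depth = 4` counts tree levels (the root protomers
plus three cleavage stages — the documented steroid, ester and nicotinamide
pathways all complete within three mass-losing steps, rearrangements being
free within a stage), and `min_mz = 50` mirrors the lower scan bound of the
ion-trap instruments this class of data comes from (the smallest fixture
peak is m/z 53). With these defaults the full tree of a C₂₀ steroid takes
well under a minute on one CPU; the trees behind the shipped results use
them unchanged.

The heuristic engine contains no randomness: iteration orders are
canonical-key sorted, so two runs with the same configuration produce
byte-identical serialized trees. The `seed` parameter only affects the
external backend's 3D embedding and the synthetic-spectrum generator.

## Annotation and scores

Peaks below the acquisition mass-range lower bound are excluded, the
relative-intensity threshold (5% or 10% for the shipped spectra) fixes the
peak set, and each remaining peak is matched against all tree ions within
±0.5 Th (ppm mode available). The precursor [M+H]⁺ is matchable like any
fragment — one documented failure mode of comparator tools is losing the
often-intense precursor peak from their score. Ambiguous matches keep all
candidate ions ranked by mass error, then by heat of formation. The weighted
score is the plain intensity sum over annotated peaks; the absolute score
counts them. Both are integer-exact on integer intensities, invariant under
peak permutation, and satisfy 0 ≤ s ≤ s_max with s = s_max exactly when
n = N.

## The synthetic-spectrum generator

`synth_spectrum()` emulates what an ion-trap MS² peak list looks like from
the engine's point of view: a subset of true fragment m/z values with
log-normal relative intensities normalized to a 100% base peak, optional
Gaussian m/z jitter, and optional decoy peaks placed at least a set distance
from any tree ion. It is deterministic under a fixed seed. It does *not*
emulate collision-energy-dependent intensities, isotope clusters, adducts
other than [M+H]⁺, or chemical noise with structure — so tests built on it
demonstrate the closure of the predict–annotate loop and the behavior of the
scores under controlled contamination, not instrument realism.

## Numerical and degenerate-input choices

* m/z values are sums of monoisotopic atomic masses (IUPAC/CODATA, shipped
  as a versioned table) divided by |charge|, **without** electron-mass
  correction — the convention under which the documented two-decimal ion
  masses (273.19 for C₁₈H₂₅O₂⁺, 145.07 for C₁₀H₉O⁺) are reproduced exactly.
  Full precision is kept internally; display rounds to two decimals. One
  caveat: C₁₁H₉O⁺ is 157.0653 u, which rounds to 157.07, while source
  tables in this field sometimes print 157.06; tests for that ion match by
  composition.
* Molecules with no protonation site yield an empty tree plus a warning,
  never an error.
* Empty spectra, negative intensities and duplicate m/z values are format
  errors with a file/line pointer; absolute intensities are normalized to
  percent-of-base-peak on input.
* Ties in selection are broken by canonical key, making every ordering
  total.

## Known limitations

* The rule inventory covers the fixture chemistry; compound classes relying
  on other eliminations (e.g. sulfonamide-specific cleavages) need
  user-supplied rules.
* The surrogate cannot distinguish subtle isomer energetics (ring strain,
  hyperconjugation); with the external PM7 backend the tree structure is
  identical but candidate ranking may differ.
* Aromaticity perception is a simple Hückel model for 5/6-rings with a
  fused-ring second pass; exotic aromatic systems (azulenes, mesoionics) are
  treated as non-aromatic, which only affects energy classification and the
  aromatic-bond exclusion in weak-bond cleavage.
* Retro-Diels–Alder is implemented for carbocyclic cyclohexenes; the
  O-heterocyclic variant relevant to flavonoid A/C-ring cleavages is not
  triggered across fused aromatic bonds, so quercetin's documented RDA ions
  are not all reproduced by the shipped registry.
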