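---
title: "Interface analysis with InterfaceMap: models, parameters and design choices"
author: "InterfaceMap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface analysis with InterfaceMap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(InterfaceMap)
```

## The problem

Molecular recognition between proteins, nucleic acids and small molecules
is mediated by interfaces: the residues and atoms of two partners in
mutual proximity and/or burying surface area against each other.
InterfaceMap characterizes an interface from both of the standard,
complementary viewpoints:

* **distance-based contacts**, which capture individual atomic
  interactions but can include incidental proximities; and
* **surface burial** (ΔSASA), which captures the overall extent and
  likely energetic relevance of the interface. A close atom pair without
  burial may be a *frustrated* proximity held in place by the surrounding
  structure rather than a favorable interaction, which is why the two
  measures are always reported together.

## Contact model

Two heavy atoms, one per selection, are in contact when their euclidean
distance is **less than or equal to** the threshold (default 4.0 Å). The
comparison is deliberately inclusive: a pair at exactly 4.0 Å counts.
Distances are carried at full precision internally and rendered to two
decimals (round-half-even) in every output.

Classification uses elements only — both in {N, O} → polar, both in
{C, S} → nonpolar, one of each → other — with **no angular criteria**.
This leniency is a feature, not a shortcut: most X-ray structures lack
hydrogens, and adding them is only stereochemically well-defined for sp²
donors; moreover, at moderate resolution the side-chain N/O assignment of
Asn and Gln is itself arbitrary. An angle-free criterion behaves uniformly
across X-ray, NMR and predicted models.

Three element decisions extend the four-element rule:

* **P → polar.** Nucleic-acid backbone phosphates then appear in the
  polar lists, where a reader expects tRNA backbone contacts.
* **Se → nonpolar**, by analogy with sulfur (selenomethionine).
* Any other heavy element (metals, halogens) places its contacts in the
  *other* class with the element printed — observed proximities are never
  silently dropped.

When either selection is entirely small-molecule (or an explicitly
selected water), the analysis switches to **ligand mode**: contacts are
left untyped and reported atom-by-atom, since polarity assignment for
arbitrary chemistry is beyond an element lookup and is left to specialized
small-molecule tooling.

In **intrachain** analyses, residue pairs fewer than two sequence
positions apart are excluded: covalently bonded neighbours are trivially
in contact. Each exclusion is noted in a message. Whether a web-based
interface analysis should do the same is debatable; here it is a
documented, logged choice.

Detection uses a uniform grid (cell width = threshold, 27-cell
neighbourhood); tests hold it equal to exhaustive O(n²) search on every
fixture. Hydrogens/deuteriums and waters are excluded at selection time so
all downstream stages see the same heavy-atom sets.

## SASA and burial

SASA is computed with a Shrake–Rupley implementation using a
**deterministic golden-spiral** point set — no randomness anywhere in the
pipeline, so reruns are byte-identical. Defaults: 960 points/atom, probe
1.4 Å, element radii C 1.70, N 1.65, O 1.40, S 1.85, P 1.90 Å (NACCESS
tradition), 1.80 Å with a warning for anything unknown. A two-column text
file can override radii. 960 points put the isolated-atom error well under
1% of the closed-form sphere area; quadrupling the count changes per-atom
values by under 2% of each atom's sphere area (per-atom values that are
*nearly zero* fluctuate by a few sampling quanta, which is why convergence
is measured against the sphere area rather than the tiny value itself).

Burial of a residue is Δ = max(0, SASA_free − SASA_complex). The free
state removes the partner selection's atoms; the complex state contains
both selections. For intrachain analyses the rest of the shared chain is
kept in *both* states, so Δ isolates the two regions' mutual occlusion
rather than folding in the scaffold's. (Computing the free state on the
fully isolated region instead would conflate region–scaffold burial with
region–region burial; the choice is documented here because either
convention is defensible.)

Δ is encoded as the integer code **min(9, ⌊Δ/10⌋)** — the unique uniform
10-Å²-wide binning with endpoints Δ ≤ 9 Å² → 0 and Δ ≥ 90 Å² → 9. Only
these codes are treated as comparable across SASA implementations: exact
areas depend on radii and sampling parameters, and per-residue agreement
with an independent implementation is tested at 3%.

## Secondary structure

Map margins carry the minimal label set a contact map needs: H (α-helix),
S (β-strand), blank otherwise. The internal assignment follows
Kabsch–Sander: the amide hydrogen is placed 1.0 Å from N opposite the
bisector of C(prev)–N and CA–N; the hydrogen-bond energy is

E = 0.084 · 332 · (1/d(O,N) + 1/d(C,H) − 1/d(O,H) − 1/d(C,N)) kcal/mol,

with a bond below −0.5 kcal/mol and a 0.5 Å clash guard. Two consecutive
i→i+4 bonds make residues i..i+3 helical; parallel/antiparallel bridges
extended into ladders of ≥ 2 give strands. The eight-state alphabet
collapses deliberately: E → S, H → H, and G, I, T and isolated bridges
(B) → blank — 3/10 helices and single bridges would add noise to a map
margin without aiding interpretation. Proline and chain-start residues
have no donor; nucleic and ligand residues are never labelled. If a local
`mkdssp` binary is configured its classic output is parsed instead,
collapsed the same way. On ideal-geometry fixtures the internal
assignment matches a reference DSSP implementation exactly; the test
suite requires ≥ 80% agreement.

## Output conventions

* **Contact lists**: three files by class (macromolecule mode) or one
  untyped file (ligand mode); lines ordered by first residue, second
  residue, distance.
* **Map cell notation**: polar count followed by a dot (`3.`), nonpolar
  count preceded by one (`.2`), mixed cells `3. .2` with a single space
  (the two tokens are standard; their combination had to be fixed here).
  A cell whose only contacts are of class *other* has no token; it keeps
  its color ("none") and its counts, so conservation still holds. Colors:
  polar-only blue, nonpolar-only yellow, mixed green; shade tiers darken
  at 1–2, 3–5 and ≥ 6 total contacts (the convention fixes the "darker
  with more contacts" rule into three reproducible tiers).
* **Ligand maps** are atom-level; cells hold the distance (2 decimals) on
  a gray scale interpolated linearly from lightest at the threshold to
  darkest at 2.4 Å (an approximate closest-approach distance), clamped.
* **CSV layout**: five margin rows/columns, in the fixed order chain,
  number, type, SS, burial. XLSX carries identical text plus the fills.
* **File names** are fixed (`contacts_*.txt`, `map_light/full.csv/.xlsx`,
  `network.graphml/json`, `view.pml/.cxc`, `windows.tsv`, `report.json`)
  so downstream scripts can rely on them.

The XLSX writer is a minimal single-sheet OOXML implementation (inline
strings + solid fills) over a minimal ZIP container; it exists because
spreadsheet editability of the maps is part of the tool's point, and it is
validated in tests by re-reading the files with an independent reader.

## Hotspot windows

Candidate binder peptides are contiguous windows of one partner's
sequence, scored by their total **atomic** contact count with the other
partner (matching the network's node-size semantics), with summed burial
codes as tie-break, then N-terminal position, then shorter length.
Lengths run 4–16: the upper bound is the practical limit for synthesizable
mimic peptides; the lower bound avoids trivially short windows. A greedy
pass keeps the top non-overlapping windows so reported peptides are
disjoint stretches. Boundary snapping to secondary-structure elements is
deliberately not attempted — in practice peptide boundaries are chosen by
inspection of the map and margins.

## Input handling

* PDB and mmCIF parsing is delegated to bio3d; multi-model files yield one
  model each and analysis uses the first (NMR convention). mmCIF assembly
  instructions (`pdbx_struct_assembly_gen`/`pdbx_struct_oper_list`) are
  parsed in-package and expanded on request; copies from non-identity
  operators are renamed `A-2`, `A-3`, … (collision-free, human-readable).
  PDB-format biological units must come pre-expanded — the format carries
  no operator instructions.
* Author numbering (with insertion codes) is used throughout, including
  for mmCIF; ranges are inclusive at both ends.
* Alternate locations collapse to the highest-occupancy conformer (first
  on ties).

## What the generated fixtures do and do not show

All test inputs are generated: ideal polyalanine helices (φ = −57°,
ψ = −47°) built from standard backbone geometry, a torsion-built
β-hairpin, a minimal 4-nucleotide strand, a 6-atom ligand, a two-model
file and an mmCIF with a 2-fold assembly operator. They exercise every
code path — contact classes, all three modes, burial, both SS classes,
assemblies — at desk scale (≤ 500 atoms), which keeps the full suite
around a minute. They are idealized: no missing atoms, no alternate
conformations beyond the dedicated test, no experimental noise, and small
interfaces (a handful of contacts rather than the hundreds of a real
protein–tRNA interface). Passing tests therefore demonstrate correctness
of the algorithms and contracts, not robustness to every pathology of
deposited structures; the parser-level defenses (element inference,
altloc collapse, chain-break detection) are each tested directly instead.

## Known limitations

* mmCIF `oper_expression` cartesian products (`(1-60)(61-88)`) are not
  expanded; such assemblies raise an explicit error.
* Only chains present in the coordinate file can be selected; there is no
  symmetry-from-space-group generation.
* No polar/apolar SASA split and no per-atom burial output (burial is a
  per-residue quantity here).
* Nucleic-acid secondary structure is not assigned.
* The contact network is exported for external tools; no layout or
  interactive rendering is attempted.
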