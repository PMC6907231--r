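---
title: "Extracting reactions from ChemDraw drawings: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting reactions from ChemDraw drawings: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

SchemeMineR turns ChemDraw drawings — standalone CDX/CDXML files or
payloads embedded in Office documents and ELN exports — into molecules
and role-assigned single-step reactions. This vignette is the package's
own account of how that reconstruction works: the geometric model and
its assumptions, the tunable parameters, the numerical and design
choices made where the problem was genuinely open, what the synthetic
test data does and does not emulate, and the known limitations.

## The drawing model

Both dialects parse into the same in-memory model, a `SchemeGraph`:
fragments (atoms and bonds with 2-D positions), text blocks and arrows.
Two conventions are fixed once and used everywhere:

* **Units.** The internal unit is the CDXML drawing point (floating).
  CDX stores coordinates as 32-bit fixed point; they are divided by
  65536 on read, so one geometry serves both dialects. The binary
  dialect's y-before-x order for 2-D positions is normalized to (x, y).
* **Orientation.** y grows *downward*, the screen convention of the
  source format. "Above the arrow" therefore means smaller y, and the
  signed perpendicular distance of the arrow projection is negative
  above the axis. Molfile output flips y back to the chemistry
  convention (y up), which also keeps wedge-derived stereo perception
  consistent with what a viewer of the drawing sees.

Object ids from the source file are remapped to one global namespace per
graph (documents can contain many payloads); originals are kept in
`origId` columns as provenance.

Unknown XML elements and unsupported binary property tags are skipped,
never fatal: of the format's hundreds of tags, extraction needs only the
~20 that are decoded (positions, bounding boxes, element, charge,
isotope, node type, bond begin/end/order/display, text, arrow endpoints
and styles). For the modern arrow object the published tag codes could
not be cross-checked against editor-written files during development;
the codes used are fixed as named constants in one table
(`R/cdx.R`) and the CDX writer and reader share them, so dialect parity
is guaranteed for everything the package writes. Reading arrows from
foreign CDX files may require adjusting those constants — a limitation
of the binary reader, not of the model.

Equilibrium and retrosynthetic arrows are parsed as plain arrows; the
drawing conventions for them carry semantics (reversibility,
disconnection) that the single-step reaction model does not represent.

## Molecule reconstruction

Fragments become connection tables with standard implicit-hydrogen
valence rules; explicitly drawn hydrogens are kept. Aromaticity is
perceived after building, so kekulized rings and explicit aromatic bonds
canonicalize identically. SMILES canonicalization, SMILES parsing and
2-D coordinate generation are delegated to OpenBabel (via ChemmineOB);
the Molfile V2000 *writer* is implemented in the package because
coordinative bonds must be emitted as the nonstandard bond type 9, which
no standard writer produces. Molfile coordinates are rescaled so the
median drawn bond length becomes 1.5 units — drawings vary widely in
absolute scale, and the median is robust to a few deliberately long or
short bonds.

**Superatoms.** An abbreviation node is replaced by its library
expansion, a SMILES with `[*]` attachment markers. The k-th marker (in
SMILES order) grafts onto the k-th drawn bond of the node (in drawing
order), preserving that bond's order and display; this makes
multi-attachment superatoms (e.g. a bridging `SO2`) unambiguous. A node
whose degree does not match the entry's attachment count is left as a
wildcard atom with a warning — never a failure. When the drawing itself
embeds an expansion (a nested fragment inside the node), that expansion
wins over the library: the drawing's own chemistry is ground truth.

**R-groups.** Labels matching `R`, `R1`, `R'`, `X`... become wildcard
(`*`) atoms. The one exception is a well-defined textual definition in
the scheme (`R = Me` with a right-hand side resolvable as a superatom),
which is substituted. Anything more complex — drawn residues with
locants, Markush tables — deliberately stays a wildcard.

**Stereochemistry** enters only through wedge/hash bond displays.
A stereocenter drawn without wedges stays undefined in the SMILES; the
package does not guess configuration from 2-D crowding.

**Coordinative bonds** (dative, e.g. N→Pd) are carried through the
chemistry table and written as Molfile bond type 9. SMILES has no
representation for them, so they are omitted from `cano_smiles`; the
metal and ligand then appear as dot-separated components. The Molfile
rendering is therefore the lossless one for organometallics.

## Dictionaries

Four dictionaries drive text interpretation, all in a plain
`key<TAB>smiles[<TAB>source]` TSV format (`#` comments): superatom
expansions, name→SMILES entries, solvents and reagents. The package
ships seed subsets (~40 superatoms, ~75 names, ~19 solvents, ~25
reagents) chosen to cover the most common laboratory vocabulary; the
loader accepts full-size files in the same format. Entries whose SMILES
does not parse are dropped with a warning, and the shipped seeds load
warning-free (a test asserts this).

Name lookup honors a source priority — curated `internal` entries win
over `corpus` entries, which win over `editor` (Name=Struct-derived)
ones — with exact-case match tried before the case-insensitive fallback
and finally a match with `.`/`,` stripped. The two-tier matching is
deliberately conservative: aggressive normalization would merge distinct
keys. Solvent-vs-reagent classification is pure set membership of the
canonical SMILES in the solvent dictionary; the seed list holds ~19
common lab solvents and is fully configurable, since no authoritative
enumeration exists.

## Role assignment geometry

For each arrow, every object's bbox center is projected into
arrow-local coordinates: `t` along the tail→head axis (0 at the tail, 1
at the head) and signed perpendicular `d`. The zones are:

| zone | condition | role |
|------|-----------|------|
| reactant side | `t < 0`, `|d| ≤ w` | starting material |
| product side | `t > 1`, `|d| ≤ w` | product |
| band | `0 ≤ t ≤ 1`, `|d| ≤ w` (extended to `t ∈ [-0.15, 1.15]` off-axis) | reagent / solvent / conditions |

with half-width `w = min(0.6 × arrow length, 4 × median bond length)`.
The source material describes the band only as "a certain area" around
the arrow, so the margins are package choices, exposed in
`defaultScanConfig()`:

* `bandFrac = 0.6` — band grows with the arrow, as chemists stretch
  arrows under crowded annotations;
* `bandCapBonds = 4` — but never beyond a few bond lengths, so parallel
  rows of a wrapped scheme stay separate;
* `axisCapFrac = 0.15` — band text is often a little wider than the
  arrow; the extension applies only off-axis (`onAxisFrac = 0.25`
  decides what counts as on-axis) so side fragments near the tail/head
  are not swallowed;
* `gapFrac = 0.25` — head-to-tail adjacency threshold when chaining
  arrows;
* `labelDistBonds = 1.5` — how far below a structure a `13a`-style
  token may sit and still be its compound label.

The formulation is projection-based, so vertical and diagonal arrows
need no special casing, and role assignment is exactly invariant under
rigid translation and positive uniform scaling of the whole drawing
(a property the test suite checks).

**Tie-breaks.** An object inside two arrows' zones in the *same* role
goes to the nearer arrow (Euclidean distance to the relevant anchor:
tail for reactants, head for products, perpendicular distance for the
band). An object claimed by one arrow's band and another arrow's side
zone goes to whichever claim is closer. The single sanctioned
double-assignment is a fragment serving as product of arrow *i* and
reactant of arrow *i + 1* — the defining pattern of a multistep chain.

**Chains.** Arrow *i* feeds arrow *j* when they share such a fragment,
when *i*'s head lies within `gapFrac` of *j*'s tail, or — for wrapped
multi-row chains where the intermediate is redrawn — when they are
consecutive in reading order (rows top-to-bottom, left-to-right within
a row) and a product SMILES of *i* reappears among *j*'s reactants.
Cycles raise an error (`"cyclic scheme"`); a drawing whose arrows form a
loop has no single-step decomposition. Steps with an empty side are
flagged `incomplete`, never dropped, and fragments in no arrow's zones
are reported as isolated molecules, so nothing disappears silently.

## Text interpretation

The condition grammar is data-driven (`inst/extdata/conditions.yaml`):
unit maps for time (`s`, `min`, `h`, `d` and their long forms) and
temperature (`°C` variants, `K`), qualitative tokens (`rt`, `reflux`,
`overnight`, `o/n`) and yield words. Tokens are split on `,`/`;` with
decimal commas (`1,5 h`) normalized first — a concession to European
documents. `overnight` is kept as a qualitative token rather than mapped
to a number; any numeric equivalent would be an invention. Within one
text block the first value of each category wins and later conflicting
values land in the residue; conflicting yields additionally warn.

A text block is classified in order: whole-string name lookup; per-token
name lookup, then condition patterns, then — for tokens that look like
line notation and parse — direct SMILES; a `^\d+[a-z]?$` token directly
below a structure (within `labelDistBonds`) is a compound label;
everything else is preserved as `unknown`/residue. No token is lost:
compounds, conditions and residue jointly account for the input.

## Containers

DOCX is an OPC zip: every member is examined, raw CDX members and
OLE-wrapped embedded objects both yield payloads (producers differ in
where they put things, so both routes are always tried). DOC is an OLE
compound file: the storage tree is walked; if that yields nothing, a
whole-file scan for the 8-byte CDX signature recovers payloads from
mildly corrupt files, marked `signature-scan` in their provenance. The
minimal CFB reader/writer and the stored-entry ZIP writer live in the
package because no installed R package handles these containers; both
implement only what embedded-object extraction needs (FAT, miniFAT,
directory tree, ministream; stored zip entries with CRC-32).

ELN XML exports carry CDXML islands and a reaction table. Field mapping
differs between ELN products and no published schema exists, so the
mapping is configuration-driven (`inst/extdata/eln-mapping.yaml`); the
shipped default covers the fixture dialect (`reactionTable/row` elements
with role/identifier/amount attributes and a closed role vocabulary).
CDXML islands are cut from the original text rather than re-serialized
through the XML tree, so payload bytes survive extraction unchanged.
Reconciliation compares the scheme's compounds with the table's as
canonical-SMILES sets and reports `missing-in-scheme`,
`missing-in-table` and `unresolved` entries; with several steps the
comparison is against the union, since table rows carry no step index.

## Exporters

Reaction SMILES follows `reactants>agents>products` with dot-joined
canonical components, agents being band structures plus text-identified
reagents and solvents. CML output carries full connection tables for
reactants/products, a `substanceList` for agents, and scalar children
for time, temperature, yield and status — status as a named property,
since CML has no standard reaction-outcome field. CDXML export
regenerates layout on a fixed grid (bond length 30 pt, arrow 90 pt
stretched as needed, band offset 20 pt): deterministic geometry makes
golden-file tests possible, and the invariant is that re-extraction of
an exported document reproduces roles, SMILES, conditions and status.
The tabular writer emits RFC 4180 CSV or a minimal XLSX (inline-string
worksheet via the in-package zip writer); rich spreadsheet formatting is
out of scope.

## The synthetic generator and what passing tests mean

`randomSpec(seed)` samples the study conditions used throughout the test
suite and the acceptance script: 1–4 step linear chains over a pool of
two dozen common organics, 1–3 reactants on the first step, 0–3 band
members (reagent names, a solvent, a drawn reagent structure),
temperature as value or `rt`/`reflux`, time in h/min, yields, and arrow
styles including dashed and crossed; layouts are horizontal chains,
wrapped chains (two steps per row, intermediate redrawn) and vertical
stacks. `generateScheme()` renders this deterministically (the seed
fully determines output bytes) with coordinate jitter up to 10% of the
bond length, bounded so no object crosses a zone boundary — tests of
boundary behavior belong to a separate adversarial suite that asserts
determinism only, not correctness. Ground truth is computed from the
spec through the dictionaries alone (canonicalization of the input
SMILES, solvent split by set membership), independent of the drawing and
extraction path.

The generator emulates clean, conventionally laid-out schemes. It does
not emulate: hand-jittered or overlapping annotations placed ambiguously
between arrows, curved or multi-headed arrows, stoichiometry grids,
Markush structures, text in images, or the serialization quirks of every
editor version. A perfect score on the synthetic suite therefore
demonstrates the geometry model, the chemistry reconstruction and the
format round-trips — not robustness to adversarial real-world layouts.

The drawn-vs-expanded superatom oracle deserves a note: for every seed
entry, the reference molecule is obtained by textually capping each
`[*]` marker with a methyl group and canonicalizing — a route that never
touches the grafting code it checks. The abbreviated drawing (methyl
stubs bonded to the abbreviation node) must extract to exactly that
canonical SMILES.

## Problem sizes and numerical choices

The acceptance script measures: round-trip accuracy and dialect parity
on 100 seeded schemes; geometry invariance on every 8th of those under
six translations/scalings; chain identity for k = 2..4 in both chain
layouts; the full superatom library against the oracle; container
round-trips on three schemes plus clean and planted reconciliations;
arrow-style flags in both dialects; and export round-trips on three
schemes. These sizes exercise every code path while keeping a full run
in the order of a minute; the per-scheme pipeline is O(objects ×
arrows) with small constants, so scaling the seed count up is linear.

Remaining numerical conventions: rectangle containment and label
adjacency use exact comparisons with a 1e-6 slack on the "below the
structure" test; CDXML coordinates are written with two decimals (fixed
format, so export bytes are deterministic); fixed-point conversion
rounds to the nearest 1/65536; text without an explicit bounding box
gets a nominal 6 pt-per-character box, which only matters for zone
membership of legacy text records.

## Known limitations

* Foreign CDX files: arrow-related tag constants are unverified against
  editor output (see above); everything else follows the published
  format.
* No OCR and no PDF input — the engine reads born-digital chemistry
  objects only.
* IUPAC name parsing is out of scope; the name dictionary resolves
  trivial names and abbreviations, and systematic names are left to
  dedicated name-to-structure tools.
* Curved, multi-head and electron-pushing arrows, retrosynthetic
  semantics, polymer brackets, enhanced stereo groups and V3000
  Molfiles are not supported.
* The shipped dictionaries are seed subsets; serious corpus work should
  load full curated libraries through `loadLibraries()`.
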