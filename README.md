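# SchemeMineR

Synthetic chemists archive most of their reaction knowledge as *drawings*:
ChemDraw schemes in manuscripts, theses, patents and electronic lab
notebooks. The structures, roles, conditions and outcomes in those
drawings are invisible to databases and machine-learning pipelines until
someone re-enters them by hand. SchemeMineR re-creates the machine-readable
chemistry from the drawings themselves: it parses ChemDraw's native CDX
binary format and its CDXML XML serialization, digs drawings out of DOC /
DOCX documents and ELN XML exports, and reconstructs molecules and
role-assigned single-step reactions with conditions and success flags,
ready for export as reaction SMILES, Molfile, CML, CDXML, CSV/XLSX or
JSON. It is aimed at groups mining their own document archives and at
anyone building reaction datasets from born-digital chemistry drawings.

## How extraction works

A drawing is reduced to a `SchemeGraph`: chemical fragments (atoms, bonds,
2-D positions), text blocks and reaction arrows. Chemistry is then
reconstructed in three stages.

**Molecules.** Each fragment becomes a connection table. Superatom labels
("OMe", "Boc", "Ts", ...) are expanded by grafting library expansions —
SMILES with `[*]` attachment markers — onto the node's neighbors;
`R`-group nodes become wildcard (`*`) atoms unless a nearby text supplies
a well-defined substitution such as `R = Me`. Wedge/hash displays carry
tetrahedral stereochemistry; coordinative (dative) bonds are preserved in
the Molfile rendering as the nonstandard bond type 9 (SMILES has no
representation for them). Every molecule gets two renderings: canonical
SMILES (`cano_smiles`) and a Molfile V2000 block (`mdl`).

**Reactions.** Every object's bounding-box center is projected into each
arrow's local frame. With *t* the normalized position along the
tail-to-head axis and *d* the signed perpendicular distance,

* *t* < 0 — reactant side (starting materials),
* *t* > 1 — product side,
* 0 ≤ *t* ≤ 1 with |*d*| ≤ *w* — the reagent/solvent band around the
  arrow, where *w* = min(0.6 × arrow length, 4 × median bond length).

Objects claimed by several arrows go to the nearest one; an object in one
arrow's band and another arrow's side zone goes to the nearer of the two,
except that a fragment may legitimately be the product of step *i* and the
reactant of step *i + 1* — that is how multistep chains are split into
single-step reactions. Band structures become reagents; band text is
interpreted: names resolve through the name→SMILES dictionary (and are
split solvent-vs-reagent against the solvent list), `80 °C` / `12 h` /
`rt` / `reflux` / `95%` tokens become conditions and yield, and the rest
is kept as a description. Arrow style sets the step status: plain →
success, dashed → planned, crossed (struck through) → failed.

**Containers.** DOCX archives are walked member by member (embedded OLE
objects are descended into), DOC compound files are walked storage by
storage with a whole-file CDX signature scan as fallback, and ELN XML
exports are split into CDXML payloads plus reaction-table records that
can be reconciled against the extraction as canonical-SMILES sets.

## Worked example

The package ships a seeded scheme generator, so a complete example needs
no input files. Seed 9 draws a three-step horizontal chain:

```r
library(SchemeMineR)
libs  <- loadLibraries()                 # seed dictionaries
fx    <- generateScheme(randomSpec(9), libs)
graph <- parseCdxml(fx$cdxml)            # or parseCdx(fx$cdx)
graph
#> SchemeGraph: 6 fragment(s) ( 34 atoms ), 7 text(s), 3 arrow(s)
#>   source: <cdxml>

res <- scanScheme(graph, libs)
for (s in res$steps) show(s)
#> ReactionStep 1 [planned]
#>   CNC(=O)OC(C)(C)C.CCO.CC=O>[H-].[Na+].ClCCl>Cc1ccccc1
#>   yield: 94 %
#> ReactionStep 2 [planned]
#>   Cc1ccccc1>CN(c1ccncc1)C>N#Cc1ccccc1
#>   yield: 43 %
#> ReactionStep 3 [success]
#>   N#Cc1ccccc1>>CC(=O)O
#>   yield: 46 %
```

Step 1 reads: three drawn reactants, sodium hydride identified from band
text as a reagent, dichloromethane recognized as the solvent, a dashed
arrow (planned reaction) and a 94% yield. The same result serializes to a
spreadsheet row per step:

```r
cat(writeTable(res$steps, "csv"))
#> reaction_smiles,reactants,reagents,products,solvents,time,temperature,yield,status,description,source
#> CNC(=O)OC(C)(C)C.CCO.CC=O>[H-].[Na+].ClCCl>Cc1ccccc1,CNC(=O)OC(C)(C)C;CCO;CC=O,[H-].[Na+],Cc1ccccc1,ClCCl,90 min,,94,planned,,
#> ...
```

`scanDocument()` runs the same pipeline on whole files — `.cdx`,
`.cdxml`, `.docx`, `.doc` or ELN XML — and `wrapInContainer()` builds the
matching synthetic containers for testing. A thin command-line front end
is included:

```sh
Rscript inst/scripts/chemscan.R scan scheme.cdxml --out smiles
Rscript inst/scripts/chemscan.R extract-embedded report.docx --outdir out/
Rscript inst/scripts/chemscan.R fixtures --seed 1 --n 5 --out fixtures/
```

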