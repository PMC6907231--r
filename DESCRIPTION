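Package: SchemeMineR
Title: Extraction of Molecules and Reactions from ChemDraw Drawings and
    Office Documents
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parses ChemDraw drawings in the CDX binary and CDXML text
    dialects, locates drawings embedded in DOC and DOCX documents and in
    electronic-lab-notebook XML exports, and reconstructs the chemistry they
    encode: molecules with superatom abbreviations expanded against a
    curated library, and single-step reactions with geometry-based role
    assignment (reactants left of the arrow, reagents and solvents in the
    band around it, products right), reaction conditions parsed from scheme
    text, and arrow-style success flags. Results export to reaction SMILES,
    Molfile, CML, CDXML, CSV, XLSX and JSON. A seeded synthetic-scheme
    generator with machine-readable ground truth supports end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    yaml,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
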