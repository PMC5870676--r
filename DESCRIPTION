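Package: modfinder
Title: Identification of Protein Modifications in 3D Macromolecular Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies protein modifications observed in 3D structures:
    modified residues (nonstandard amino-acid components such as
    phosphoserine), attachment modifications (glycans, metal ions and other
    chemical components covalently linked to polymer residues) and
    cross-links (disulfide and isopeptide bonds).  Detection is driven by a
    declarative XML modification dictionary listing the chemical components
    and atom pairs involved; covalent bonds are inferred from coordinates by
    a covalent-radius distance criterion.  Reads PDB and mmCIF files,
    exports per-entry TSV/JSON annotation and per-chain sequence tracks,
    scans directories in batch, and generates synthetic structure fixtures
    with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
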