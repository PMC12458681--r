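Package: InterfaceMap
Title: Macromolecular Interface Contact, Burial and Hotspot Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Offline analysis of macromolecular interfaces from PDB or mmCIF
    coordinates. Given two chains, or two regions of one chain, the package
    detects all heavy-atom contacts within a distance threshold (default
    4.0 Angstrom, inclusive), classifies each contact as polar, nonpolar or
    mixed by the participating elements, computes per-residue interface-buried
    solvent-accessible surface area with a deterministic Shrake-Rupley
    implementation and encodes it as an integer 0-9 code, assigns
    alpha-helix/beta-strand labels with an internal Kabsch-Sander style
    procedure, and writes contact lists, editable light and full 2D contact
    maps (CSV and XLSX), a residue contact network (GraphML/JSON), PyMOL and
    ChimeraX visualization scripts, and a ranking of contiguous sequence
    windows (candidate binder peptides) by interface-contact density.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
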