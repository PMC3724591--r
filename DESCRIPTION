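Package: protplot
Title: Protein Mutation Lollipop Plots with Alignment Conservation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Visualize amino-acid variants on a protein schematic.
    Reads tab-separated mutation, domain-architecture and
    post-translational-modification files plus an optional aligned
    multi-FASTA, computes a reference-anchored per-position conservation
    score (the fraction of non-reference sequences matching the reference
    residue), annotates each variant with its domain membership and PTM
    overlap, and renders a deterministic multi-track figure (lollipop
    mutation tracks, domain boxes, PTM marks, reference letters,
    conservation track) to SVG, PDF or PNG, with zooming into any residue
    window. Includes a synthetic-fixture generator and a command-line
    entry point.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    seqinr,
    tools,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
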