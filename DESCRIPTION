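Package: genestructr
Title: Aligning Eukaryotic Gene Structures on Protein Multiple Sequence
    Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects intron positions and reading-frame phases from
    exon/intron gene structures onto a protein multiple sequence alignment,
    groups introns shared at identical alignment position and phase into
    common-intron clusters, and renders the resulting gene-structure
    alignment as plain text, as a binary presence/absence FASTA matrix for
    phylogenetics, as SVG diagrams at exon or nucleotide resolution, and as
    PyMOL colouring scripts that map conserved intron positions onto a
    protein 3-D structure.  Gene structures are read from a documented
    Scipio-style YAML subset; a synthetic family generator produces
    ground-truth-annotated test inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    jsonlite,
    optparse
Config/testthat/edition: 3
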