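Package: mtphylo
Title: Mitochondrial DNA Phylogeography of Domestic Swine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mitochondrial D-loop and cytochrome b phylogeography
    of domestic swine and wild boar: variable-site detection and
    classification, haplotype collapsing and per-breed summaries, haplotype
    and nucleotide diversity with Watterson's theta, Kimura 2-parameter
    distances, Nei-Gojobori synonymous and non-synonymous distances under
    the vertebrate mitochondrial code, Neighbor-Joining trees with
    nonparametric bootstrap support and outgroup rooting, Nei net
    between-clade distances, and molecular-clock divergence dating via
    T = K/2r with region-specific substitution rates. Includes a seeded
    two-clade sequence simulator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
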