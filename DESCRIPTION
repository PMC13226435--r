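Package: scaffchron
Title: Time-Resolved Scaffold Diversity and Chemical-Space Mapping for
    Compound Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to chart how the structural content of a compound
    library changes over time. Standardizes SMILES collections (desalting
    and charge neutralization), extracts Bemis-Murcko scaffolds and
    generic carbon frameworks, quantifies scaffold diversity with Shannon
    entropy and equitability, builds per-year chronicles of new molecules
    and scaffolds with year-over-year growth rates, and renders era-sliced
    two-dimensional chemical-space maps from circular fingerprints via
    principal component analysis and t-distributed stochastic neighbor
    embedding. Includes a seeded synthetic-library generator emulating the
    skewed scaffold frequencies and exponential growth of public
    bioactivity databases, so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    Rtsne,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
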