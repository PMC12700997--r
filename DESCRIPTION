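Package: caulotraits
Title: Lifecycle Asymmetry, Convergent Gene Loss, and Phototrophy Screens
    for Caulobacterales Comparative Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytics for comparative studies of dimorphic Caulobacterales
    bacteria. Quantifies replicative (a)symmetry from tracked single-cell
    lineage tables (degree-of-asymmetry statistics, generation-time
    modality, constriction-site position summaries), builds genome-by-gene
    family presence/absence matrices from KEGG-ortholog and reciprocal
    best-hit evidence, screens species trees for gene modules convergently
    lost in independent lineages under Dollo parsimony, and calls
    phototrophic and photoautotrophic genetic potential including
    photosynthesis gene-cluster detection and synteny scoring. Synthetic
    data generators with known planted truth (dimorphic lineages, trees
    with clade-restricted loss modules, annotated genomes with planted
    photosynthesis gene clusters) make every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    mclust,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
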