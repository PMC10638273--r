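Package: PolyProfile
Title: Phylogenetic Profiling of Multi-Subunit Complex Evolution
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracing the evolution of multi-subunit protein
    complexes (exemplified by the Polycomb repressive complexes PRC1 and
    PRC2) across a set of species by phylogenetic profiling. Provides
    domain-architecture based ortholog confidence calling from HMMER
    domtblout tables, species-overlap duplication/speciation labelling of
    gene trees with orthologous-group delineation and inference of presence
    in the last eukaryotic common ancestor (LECA), three-state
    presence/putative/absence profile matrices with complex-completeness
    scoring and five-way species categorization, phi-coefficient
    co-occurrence analysis with average-linkage clustering, and a seeded
    generator of coupled Dollo-loss synthetic data sets for end-to-end
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
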