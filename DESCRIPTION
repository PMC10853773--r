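Package: dndscape
Title: Comparative Genomics of Dnd Phosphorothioate Defense Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstruction and analysis of the gene-neighborhood,
    clustering, phyletic and phylogenetic signals that characterise the
    DndABCDE phosphorothioate modification and DndFGH restriction systems
    of bacteria and archaea. Provides anchored gene-neighborhood extraction
    from annotated genomes with distance, directionality and phylum-spread
    validity filters; threshold-graph single-linkage protein clustering with
    coverage (L) and score (S) semantics and evidence-based singlet merging;
    species-level deduplicated presence/absence profiling with module
    co-occurrence summaries; column-wise Shannon entropy profiling of
    alignments under full and reduced amino-acid alphabets; neighbor-joining
    trees, Robinson-Foulds distances, operonic-pair clade congruence and
    capture-clade counting; and seeded generators for synthetic genomes,
    clade-structured protein families, coevolving gene pairs and
    composition-controlled alignments with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    phangorn,
    igraph,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
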