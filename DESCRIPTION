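Package: leafendo
Title: Two-Group Endophyte Community Analysis: Diversity, Sensitive Taxa,
    Co-Occurrence Networks, and Assembly Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable inference chain for two-group amplicon sequence
    variant (ASV) count tables, motivated by plant endophyte microbiome
    surveys contrasting healthy and non-healthy host tissue. Covers alpha
    diversity with group tests, Bray-Curtis ordination (NMDS) and PERMANOVA,
    TMM/CPM normalization with negative-binomial likelihood-ratio
    differential abundance, indicator species analysis (IndVal) and the
    health-sensitive ASV intersection, thresholded Spearman co-occurrence
    networks with greedy modularity and topology metrics, Levins' niche
    breadth, Sloan neutral community model fitting with bootstrap confidence
    intervals, and C-score null-model analysis with sequential swap
    randomization. A synthetic community generator with known ground truth
    (neutral assembly, selection perturbation, differential taxa, correlated
    taxon blocks) makes every stage verifiable without raw sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vegan,
    igraph,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
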