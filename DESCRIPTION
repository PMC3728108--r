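Package: CoevNet
Title: Coevolving Amino Acid Sites: Detection, Bootstrap Support,
    Networks and Sector Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects intra- and inter-protein coevolving amino acid site
    pairs from multiple sequence alignments using a divergence-time
    corrected BLOSUM covariation statistic with a simulated-alignment
    null distribution, assigns reliability to each pair with a
    non-parametric phylogenetic bootstrap, builds coevolution networks
    with degree, closeness and betweenness centralities, tests the
    statistical independence of coevolving site groups between clades
    with relative-entropy statistics, and maps site groups onto protein
    structures (proximal-carbon compactness and secondary-structure
    enrichment). Includes a synthetic-data module that simulates trees,
    neutrally evolving alignments with planted covarying site pairs,
    reverse-translated coding alignments and toy structures, so the
    whole pipeline can be exercised and calibrated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    igraph,
    bio3d,
    seqinr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Phylogenetics, Alignment, NetworkInference, StructuralPrediction
RoxygenNote: 7.3.3
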