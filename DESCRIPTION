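Package: kbscan
Title: Affinity-Scored Scanning and Cluster Analysis of NF-kB Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designates strong and weak kB sites (NF-kB binding elements,
    consensus GGGRNNYYCC) in promoter and enhancer sequences using a 10-mer
    affinity Z-score lookup table, relates clusters of such sites to ChIP-seq
    occupancy through cumulative Z-scores in dynamic windows and Pearson
    correlation curves, projects equilibrium site occupancy from nuclear
    transcription-factor concentration and dissociation constant, and scores
    DNA-pulldown mass-spectrometry peptide-count matrices for enriched
    proteins. A synthetic-data module generates sequences with planted motif
    clusters, occupancy scores, Z-score tables and count matrices with known
    ground truth so every stage of the analysis can be exercised and
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
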