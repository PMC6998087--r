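Package: primerscout
Title: Discovery of Universal-Primer-Evading SSU rRNA Groups and Targeted
    Primer Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mining meta-transcriptomic small-subunit (SSU) rRNA
    reads with intact 5' termini for prokaryotic lineages that evade the
    universal forward primers 8F and Arch21F.  Extracts and classifies
    primer-binding sites with IUPAC-aware mismatch patterns, clusters reads
    into OTUs and screens them for novel primer-mismatched groups, designs
    targeted and degenerate forward primers (Wallace or nearest-neighbor
    melting temperature, degeneracy control, specificity checks), and
    quantifies novelty of near-full-length 16S rRNA sequences with
    uncorrected pairwise distances and candidate-phylum calls.  Includes a
    deterministic synthetic-read generator with ground-truth manifests so
    the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
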