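Package: hgtclock
Title: Dating Gene Acquisitions with DTL Reconciliation and HGT-Based Clock Model Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing the acquisition of horizontally transferred gene
    families on dated species phylogenies. Provides a multiheme-cytochrome census
    based on C-X-X-C-H heme-binding motif scanning of protein FASTA files, minimum
    cost Duplication-Transfer-Loss (DTL) parsimony reconciliation of rooted gene
    trees against rooted species trees with transfer extraction, temporal
    compatibility scoring of posterior chronogram ensembles against HGT
    donor-older-than-recipient constraints (including clock-model ranking and
    constrained age posteriors), and seeded synthetic-data generators (birth-death
    chronograms, posterior-like age-jittered ensembles, planted transfers, DTL gene
    trees, and motif-planted proteomes) so the whole pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    withr,
    yaml
Suggests:
    phangorn,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
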