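Package: virlink
Title: Detection and Classification of Viral and Bacterial DNA in Protistan
    Single Amplified Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contamination triage for protistan single amplified genomes
    (SAGs). Detects and classifies non-eukaryotic (bacterial and viral)
    contigs using an in-package bottom-s MinHash sketcher with Mash-style
    distances, a per-contig evidence classifier (viral ORF fraction,
    metagenome read-recruitment ratio, k-nearest-neighbour viral score,
    ssDNA coverage rule, bacterial reference and ORF-majority rules), a
    contig similarity network with Louvain community clustering, cluster
    categorisation and viral lowest-common-ancestor labelling, a Poisson
    droplet co-sorting expectation model for flow sorting, and the
    association statistics layer (contingency chi-square tests, one-way
    ANOVA with Tukey letter displays, Mann-Whitney tests). Ships a
    synthetic SAG community generator with planted ground truth so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
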