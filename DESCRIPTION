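Package: pgpmkit
Title: Fragment Recruitment and Compatibility-Guided Design of Plant
    Growth-Promoting Microbial Consortia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the representation of candidate plant
    growth-promoting microorganisms (PGPMs) in shotgun metagenomes and for
    assembling multi-strain inoculant consortia from pairwise compatibility
    assays. Implements q-gram filtered fragment recruitment of metagenome
    reads onto reference genomes with a strict identity threshold, removal
    of recruited reads piled up at abnormally highly covered loci (such as
    conserved rRNA repeats), per-billion-read normalization of recruitment
    counts with environment-level pooling, and average-linkage clustering
    of the resulting abundance matrices. A second set of tools loads
    transcribed strain, compatibility, and biostimulant-response tables,
    builds compatibility graphs, enumerates maximal pairwise-compatible
    function-covering consortia, validates published consortium designs,
    and ranks bioactive compounds by their prebiotic support of a
    consortium's members. A seeded simulator generates reference genomes,
    divergent read sets with planted repeat elements, and compatibility
    matrices with planted cliques for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
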