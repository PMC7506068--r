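Package: depthmeta
Title: Depth-Partitioned Hybrid Metagenome Assembly, Gene Catalogs and Genome Binning
Version: 0.1.0
Authors@R: person("depthmeta", "developers", email = "depthmeta@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully deterministic pipeline for depth-based hybrid
    assembly of short and long metagenomic reads. Reads are mapped to a merged
    short-read assembly, stratified into coverage-depth phylotypes, assembled
    per stratum with a de Bruijn unitig assembler, merged with long reads by
    contig anchoring, de-duplicated and polished with short-read pileups.
    Downstream stages predict open reading frames, build non-redundant gene
    catalogs by greedy identity/coverage clustering, assign taxonomy by a
    bitscore-margin lowest-common-ancestor rule, bin contigs by tetranucleotide
    frequency plus per-sample depth, and score bins with single-copy-marker
    completeness and contamination. A ground-truthed synthetic community
    generator (paired 150-bp short reads, error-prone long reads, planted
    markers, repeats and taxonomy) makes every stage testable offline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
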