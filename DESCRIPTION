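Package: amplicall
Title: Genotyping by Multiplexed Amplicon Sequencing for Marker-Assisted Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotype calling from multiplexed amplicon sequencing reads for
    marker-assisted selection panels. Implements the full analysis path from raw
    barcoded FASTQ reads to per-sample, per-marker genotype calls: barcode
    demultiplexing, forward-primer marker assignment, banded pairwise alignment of
    inserts to reference amplicons, per-site A/C/G/T/N allele counting, and
    genotype calling anchored on in-run positive-control read fractions, with
    support for dominant null-allele markers, multi-SNP amplicons, and the
    polyploid expected allele-fraction model for primers that co-amplify one to
    three homoeologous genomes. Includes fusion-primer construction for
    two-round barcoded library builds, a synthetic read simulator with known
    ground truth, and genotype concordance computation against external call
    sets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
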