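Package: gbsnp
Title: De Novo Genotyping-by-Sequencing Simulation, Mock-Reference Variant
    Calling and Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reference-free variant discovery from
    genotyping-by-sequencing (GBS) data, together with a read simulator and
    a truth-based evaluation harness. The pipeline dereplicates and clusters
    reads into a mock reference of consensus GBS fragments, maps reads back
    with a k-mer seeded banded aligner, calls bi-allelic SNPs and indels
    from per-individual pileups, screens likely homolog (paralog) variants
    with a binomial allele-depth Z-score, infers ploidy from allele-balance
    distributions at heterozygous loci, and scores calls against simulated
    truth (Type I error, Type II error, overall accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
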