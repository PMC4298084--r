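Package: asmeval
Title: Probabilistic Evaluation of De Novo Transcriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reference-free and reference-based evaluation of de novo
    transcriptome assemblies from RNA-Seq reads. The reference-free score is
    the log joint probability of an assembly and its reads under a generative
    model combining an RSEM-style read likelihood (fitted by EM), a
    coverage-consistency correction, an assembly prior built from a Poisson
    read-coverage process over negative-binomially distributed transcript
    lengths, and a BIC penalty. Reference-based measures include contig- and
    nucleotide-level recall/precision/F1 against a reference transcript set,
    a weighted k-mer compression score, construction and estimation of the
    true assembly implied by read origins, and generators for simulated
    transcriptomes, reads and perturbed assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
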