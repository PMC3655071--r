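Package: depthsat
Title: Read-Depth Saturation Analysis for De Novo Transcriptome Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to ask how many reads a de novo transcriptome assembly
    needs. Simulates paired-end RNA-seq libraries with realistic artifacts,
    filters reads (mean-Phred, adapter, low-complexity rules), cuts randomized
    nested subsamples to form a depth ladder, assembles each subset with a
    small de Bruijn unitig assembler with a static k-mer coverage cutoff,
    computes assembly summary statistics (N50, loci, GC), and scores
    completeness against clusters of conserved single-copy orthologs by
    translated local alignment, ORF extraction requiring start and stop
    codons, and a ratio-based full-length size-range classification. The
    result is a saturation curve of genes detected and genes assembled
    full-length as a function of read count.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
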