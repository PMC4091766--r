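Package: gapweld
Title: Gap Closing for Draft Genome Assemblies Using Alternative Datasets
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closes N-run gaps in draft genome assemblies by aligning the
    flanks of each gap against alternative sequence datasets (contigs from
    alternative assemblies, long reads) with nucleotide BLAST, selecting the
    best gap-spanning sequence, and editing scaffolds in conflict-safe
    multiple rounds with full logging and final statistics. Supports negative
    gaps caused by overlapping contig ends, three-criterion validation of
    closed gaps against a reference genome, an exact affine-gap local
    alignment oracle, and a synthetic fixture generator that produces
    reference/draft/dataset triples with known ground truth. Requires the
    BLAST+ command line tools (makeblastdb and blastn) on the PATH.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    testthat (>= 3.0.0),
    withr
SystemRequirements: BLAST+ >= 2.2.28 (blastn and makeblastdb on PATH)
Config/testthat/edition: 3
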