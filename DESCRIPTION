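Package: tandemcheck
Title: Assembly Validation for Tandem Gene Arrays with k-mer and
    Read-Depth Audits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to audit genome assemblies of tandemly duplicated gene
    arrays, the hardest regions for shotgun assemblers.  Includes a
    synthetic-data generator that builds haploid tandem arrays of
    near-identical gene variants with transposable-element spacers,
    short/long read simulators with recorded provenance, a misassembly
    injector and a PCR template-switching simulator; a k-mer subtraction
    audit that flags assembly k-mers absent from a high-coverage read
    set; read-depth audits (zero-coverage regions, consistent
    mismatches) and a depth-calibrated copy-number caller for panels of
    near-identical paralogs; a single-crossover chimera detector that
    explains candidate variants as PCR recombination artifacts; and a
    seed-and-extend annotator that enumerates gene copies and masks
    repeats against a TE library.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    rtracklayer,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
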