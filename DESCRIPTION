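Package: promex
Title: Batch Extraction of Gene Promoter and Flanking Sequences from Genome Assemblies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts user-defined upstream and downstream flanking sequences
    (promoter regions) for arbitrary gene lists from a reference genome FASTA
    and a GFF3 annotation, with explicit strand orientation and
    chromosome-boundary semantics. Gene identifiers are matched against
    annotation attributes with version-suffix fallback, one representative
    record (gene preferred over mRNA) is chosen per gene, and flanks are
    extracted in a single vectorized pass. Results are written as a structured
    CSV together with a per-run summary reporting upstream and downstream
    extraction error rates. Includes a deterministic synthetic
    genome/annotation fixture generator with planted ground-truth flanks, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    optparse,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
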