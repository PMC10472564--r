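Package: prohintr
Title: Protein-Evidence Hints, Training Genes and Chunked Prediction for Genome Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bespoke computational stages of a protein-based
    genome annotation pipeline: parsing spliced protein-to-genome alignments
    (including a compact residue-level dialect), scoring candidate introns by
    border-alignment conservation (IBA) and mapping coverage (IMC) with
    frameshift and in-frame-stop penalties, two-tier hint classification for
    a gene predictor, training-gene selection with flanking-region refinement,
    overlap-chunked parallel prediction planning with duplicate-free merging,
    multi-level gene-set accuracy evaluation (sensitivity, specificity, F1 at
    gene, transcript and exon level), and a seeded synthetic-data generator
    with known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
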