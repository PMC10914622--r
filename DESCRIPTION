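Package: rejoinr
Title: Joining Metagenome-Assembled Viral Contigs via Assembler End Overlaps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joins contigs from a single de Bruijn graph metagenome assembly
    by detecting shared fixed-length end sequences (maxK for metaSPAdes and
    MEGAHIT, maxK-1 for IDBA_UD), validating candidate joins with sequencing
    coverage ratios and paired-read spanning evidence, and classifying each
    query contig as self_circular, extended_circular, extended_partial,
    extended_failed or orphan_end. Includes a ground-truthed synthetic
    community generator (genomes with direct terminal repeats, subpopulation
    variants, repeat-induced fragmentation, simulated paired reads), a
    zero-coverage gap masker, and a benchmark evaluator implementing
    good/problematic/contaminated labels, a normalized contamination rate,
    pairwise confusion metrics and RPKM.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
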