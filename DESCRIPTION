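Package: plastomeDivGap
Title: Diversity-Gap Marker Discovery from Plastid Genomes and Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of closely related plastid genomes and
    discovery of species-diagnostic DNA barcodes. Computes plastome summary
    statistics (GC content by quadripartite partition, microsatellites at
    MISA-style unit thresholds, exact forward and palindromic long repeats,
    indel and SNP catalogues from a multiple alignment, codon usage with
    RSCU), scores sliding windows by the Diversity Gap (interspecific
    nucleotide diversity from an aligned genome trio minus intraspecific
    diversity estimated from read pileups), profiles allele types and
    frequencies around a target locus from sequencing reads, and classifies
    amplicon sequences to species using diagnostic indel rules. A seeded
    synthetic-data generator emulating a trio of closely related circular
    genomes with heteroplasmic read pools makes every stage testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tools,
    methods,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
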