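Package: lanmine
Title: Genome-to-Metabolite Mining of Class II Lanthipeptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery pipeline for class II lanthipeptides from (archaeal)
    genomes: mines small precursor open reading frames adjacent to annotated
    lanM synthetase loci, enumerates post-translationally modified core-peptide
    species (dehydration, methylation, dehydrogenation), matches them to
    high-resolution MS1 peaks within a ppm tolerance, and infers thioether
    ring topology from ring-aware b/y fragment annotation and simulated
    reductive desulfurization (NaBH4/NaBD4). Includes exact molecular-formula
    and monoisotopic-mass arithmetic, readers and writers for FASTA, GFF3 and
    MGF, and seeded synthetic-data generators (genomes with planted precursors
    and decoys; MS1/MS2 spectra with ppm jitter and noise peaks) so that every
    stage of the pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr
Config/testthat/edition: 3
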