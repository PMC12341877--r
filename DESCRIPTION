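Package: pinekit
Title: Linkage-Map Genome Anchoring, Population Genomics and Mixed-Model
    Association for Conifer Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for building chromosome-scale pseudomolecules from a
    fragmented conifer assembly and multiple parental linkage maps (marker
    filtering and assignment, chimeric-contig detection and splitting,
    transcript-evidence contig joining, weighted ordering and orientation,
    AGP emission), together with the population-genomic analyses typically
    run downstream: variant filtering with an exact Hardy-Weinberg test,
    windowed diversity statistics (segregating sites, nucleotide diversity,
    Tajima's D), linkage-disequilibrium decay and LD-based effective
    population size trajectories, LD pruning, principal component analysis,
    and EMMAX-style mixed-model genome-wide association with identity-by-state
    kinship. A forward-in-time diploid Wright-Fisher simulator with
    recombination, together with genome/map/transcript generators, provides
    fully synthetic inputs with known ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    vcfR,
    zoo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
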