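Package: genarch
Title: Genome Architecture Analyses for Inbred Line Panels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of natural variation in genome
    architecture for panels of inbred lines derived by full-sib mating
    from a natural population. Provides a synthetic panel generator
    (inbreeding with recombination, deletion-biased indels, genetically
    diverged polymorphic inversions, an outgroup for polarization,
    endosymbiont infection status, and phenotypes), multi-caller variant
    integration with haplotype binning and freeze-quality filtering,
    population-genomic statistics (segregating-site profiles, nucleotide
    and indel diversity, divergence, site-frequency spectra, karyotype
    diversity, variant clustering, recombination and chromatin-domain
    analyses), genomic relationship matrices with principal-component
    structure and Tracy-Widom significance, linkage-disequilibrium decay
    and long-range LD, functional consequence and protein-damage
    annotation against toy gene models, and inversion- and
    endosymbiont-adjusted mixed-model, burden, and SKAT association
    mapping.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
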