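Package: snpanel
Title: SNP Genotyping Panel Design and Population-Genetic Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building fixed-size SNP genotyping panels from
    multi-sample VCFs and for validating them with standard
    population-genetic analyses. Implements a quality/MAF/missingness/
    heterozygosity/spacing marker screening cascade with ranked selection,
    design and in-silico validation of overlapping 110 bp liquid-phase
    capture probes under GC and genome-homology constraints, per-group
    diversity summaries (MAF, PIC, observed and effective allele numbers,
    observed and expected heterozygosity), linkage-disequilibrium decay
    curves, genomic-relationship-matrix PCA, a binomial admixture model
    fitted by EM with cross-validated choice of the number of ancestral
    clusters, and neighbor-joining trees on genotype p-distances with
    bootstrap support. A seeded simulator of structured diploid
    populations (Balding-Nichols differentiation with optional admixture)
    provides reference FASTA and VCF inputs with known truth for testing
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    graphics,
    optparse,
    stats,
    utils,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
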