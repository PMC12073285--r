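Package: ssrkit
Title: SSR Marker Development and Evaluation from Whole-Genome Resequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines simple sequence repeat (SSR, microsatellite) loci from
    population resequencing data and evaluates them as codominant markers.
    Detects perfect tandem repeats in nucleotide sequences under
    MISA-compatible minimum-repeat criteria, extracts long insertion/deletion
    alleles from population VCF files, applies quality-control and
    candidate-selection rules, designs and filters flanking PCR primers,
    computes per-locus diversity statistics (allele counts, effective
    alleles, Shannon index, heterozygosities, fixation index, polymorphism
    information content), performs population-structure analyses (Nei's
    genetic distance, UPGMA clustering, hierarchical AMOVA, pairwise Fst,
    Evanno delta-K), and builds binary fingerprint matrices with a
    discrimination rate. Includes deterministic synthetic-data generators
    (planted SSR references, population VCFs, Balding-Nichols genotype
    matrices) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    vcfR,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
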