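Package: mhpaternity
Title: Noninvasive Prenatal Paternity Testing with Microhaplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines prenatal paternity noninvasively from massively
    parallel sequencing of short multi-SNP markers (microhaplotypes).
    Provides microhaplotype genotyping from amplicon alignments of mother,
    alleged father and maternal plasma (read filtering, base-quality
    masking, partial/total haplotype pairing, rule-table genotype calls),
    detection of the foetal paternal haplotype in the maternal/foetal
    plasma admixture with foetal-fraction estimation, per-locus paternity
    indices and the cumulative probability of paternity with
    exclusion/inconclusive/inclusion decision logic, population reference
    panel statistics (haplotype frequencies, effective allele numbers,
    Hardy-Weinberg and linkage-equilibrium screening from phased VCF
    panels), true/false paternity simulations and ROC cross-evaluation,
    and a synthetic-data generator (phased panels, Mendelian families,
    error-bearing aligned reads including admixed plasma) so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
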