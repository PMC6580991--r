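Package: survscan
Title: Within-Generation Selection Scans on Replicate Survivor Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects loci under viability selection within a single
    generation by comparing allele frequencies of survivor populations
    against the originally sown population (or against each other) across
    replicate field plots. Implements genotyping-by-sequencing quality
    filters, allele-frequency estimation from individual genotypes and from
    pooled sequencing read counts, a per-SNP two-population F_ST statistic
    with a 2N*F_ST chi-square test, a replicate-intersection selection rule
    with a combined false-discovery-rate estimate l*P^n/d, Fisher exact
    confirmation, principal-component views of population structure, and a
    balanced two-way analysis of variance of treatment effects on allele
    frequencies. Includes a forward simulator of within-generation
    viability selection with GBS read and pooled-sample sequencing models
    for calibration and power analysis.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
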