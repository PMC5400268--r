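Package: timberid
Title: Forensic Timber Identification from Chloroplast Haplotypes and STR Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-tier forensic identification databases for tropical timber.
    Builds a chloroplast-DNA haplotype database for geographic-origin
    inference from aligned intergenic spacer sequences, and a short tandem
    repeat (STR) profiling database for individual identification:
    allele-frequency databases with a 5/(2N) minimum-frequency floor,
    locus diversity and forensic parameters, Monte-Carlo exact tests of
    Hardy-Weinberg and linkage equilibrium, Weir-Cockerham coancestry and
    inbreeding coefficients with locus bootstrap, random match
    probabilities under the subpopulation-cum-inbreeding model,
    database conservativeness testing with coancestry adjustment sweeps,
    and Bayesian population assignment with Dirichlet posterior-predictive
    genotype likelihoods. Includes a hierarchical-Dirichlet simulator that
    emulates a two-region, 27-population sampling design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
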