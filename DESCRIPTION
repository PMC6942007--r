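Package: stratsim
Title: Simulating Population Stratification and Its Impact on Genomic
    Prediction and Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generative model for admixed cohorts in which allele
    frequencies and environment are both associated with ancestry,
    together with the analyses such data are meant to stress: genotype
    principal components and their sample-size-dependent detectability,
    projection of cohorts into a reference haplotype-sharing basis,
    restricted maximum likelihood ridge-regression marker BLUP for
    genomic prediction with and without principal-component correction,
    and two-sample Mendelian randomization under differential structure
    correction.  Includes scenario engines that quantify when principal
    component correction helps, is neutral, or harms prediction and
    causal estimation, plus exporters (VCF, TSV, JSON configs) and a
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
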