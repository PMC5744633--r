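Package: strainmatch
Title: Strain Identification from Sparse SNP Genotype Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies inbred strains (accessions) from sparse, low-coverage
    SNP genotype calls by matching a query sample against a panel genotype
    database with a binomial likelihood statistic. Reports a chi-squared
    likelihood-ratio ambiguity set of strains statistically indistinguishable
    from the top hit, screens samples for hybrid (F1/F2) ancestry via their
    heterozygosity, and identifies the two parents of hybrid individuals by
    running the matcher in genomic windows. Includes a database builder for
    multi-sample VCF panels, readers for single-sample VCF and positional
    genotype tables with Phred-scaled (PL) call confidences, a synthetic-data
    generator for inbred panels, error-prone sparse queries and F2
    recombinants, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    vcfR,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
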