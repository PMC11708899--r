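Package: ancientpop
Title: Population-Structure Analyses for Ancient DNA Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing population structure in low-coverage ancient
    DNA cohorts genotyped on SNP panels. Implements f3/f4 statistics with
    weighted block-jackknife standard errors and a cladality screen,
    qpAdm-style admixture-proportion estimation with a distal model search,
    principal component analysis with least-squares projection of sparse
    pseudo-haploid genomes, a geographically matched resampling test for
    ancestry heterogeneity in eigenvalue-scaled PC space, READ-style kinship
    classification from pairwise mismatch rates, genetic sexing from X/Y read
    counts, and Y-chromosome haplogroup scoring. Ships a synthetic-data
    generator (Balding-Nichols drift, admixture with optional sex bias,
    pseudo-haploid sampling, pedigrees, read counts, spatially clustered
    reference panels) so every analysis can be exercised with known truth,
    plus the metadata table of a 91-individual North Pontic cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere
Config/testthat/edition: 3
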