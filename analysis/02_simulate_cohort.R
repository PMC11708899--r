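#!/usr/bin/env Rscript
# Simulate a small synthetic cohort with known truth: three-source
# admixture (farmer-like, steppe-like, east-like), pseudo-haploid calls
# with missingness, and a metadata table with geography and dates. Writes
# an EIGENSTRAT bundle so every later step can run from files.

suppressPackageStartupMessages(library(ancientpop))
dir.create("results/simulated", showWarnings = FALSE, recursive = TRUE)
seed <- 42

specs <- list(
  pop_spec("farmer", f = 0.08),
  pop_spec("steppe", f = 0.08),
  pop_spec("east",   f = 0.15),
  pop_spec("target", f = 0.01,
           admix = c(farmer = 0.5, steppe = 0.4, east = 0.1)))
truth <- simulate_frequencies(1500, specs, seed = seed)
mat <- sample_genotypes(truth, c(farmer = 6, steppe = 6, east = 4, target = 8),
                        missing_rate = 0.15, seed = seed + 1)
write_eigenstrat(mat, "results/simulated/cohort",
                 group = attr(mat, "group")[mat$samples])

geo <- simulate_geo_dates(length(mat$samples), center = c(48.5, 33),
                          radius_km = 400, date_window = c(-700, -300),
                          seed = seed + 2)
geo$id <- mat$samples
write.table(geo, "results/simulated/metadata.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

jsonlite::write_json(
  list(seed = seed,
       true_weights = list(farmer = 0.5, steppe = 0.4, east = 0.1),
       n_snps = 1500, missing_rate = 0.15),
  "results/simulated/truth.json", auto_unbox = TRUE, digits = NA)

cat("Simulated", length(mat$samples), "pseudo-haploid samples x",
    nrow(mat$snps), "SNPs ->", "results/simulated/cohort.{geno,snp,ind}\n")
cat("True target admixture: 0.5 farmer + 0.4 steppe + 0.1 east\n")
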