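#!/usr/bin/env Rscript
# READ-style kinship on a simulated pedigree: a duplicated sample, a
# parent-offspring trio and unrelated founders, classified from windowed
# pseudo-haploid mismatch rates.

suppressPackageStartupMessages(library(ancientpop))
dir.create("results", showWarnings = FALSE)
seed <- 505

tr <- simulate_frequencies(25000, list(pop_spec("p", f = 0.05)), seed = seed)
sites <- select_kinship_sites(tr$freq_auto["p", ], 0.1)
ped <- data.frame(id = c(paste0("F", 1:8), "kid", "dupA"), pop = "p",
                  father = c(rep(NA, 8), "F1", NA),
                  mother = c(rep(NA, 8), "F2", NA),
                  duplicate_of = c(rep(NA, 9), "F3"))
g <- simulate_pedigree(tr, ped, seed = seed + 1)
cls <- classify_kinship(pairwise_p0(g, sites))
write.table(cls, "results/kinship_classes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

related <- cls[cls$class != "unrelated", ]
cat(sprintf("%d of %d pairs classified related (MAF>0.1 sites: %d):\n",
            nrow(related), nrow(cls), length(sites)))
print(related[, c("id1", "id2", "norm_p0", "class")], row.names = FALSE)

merged <- merge_identical(g, c("F3", "dupA"), kinship = cls)
cat(sprintf("Merged duplicate pair F3/dupA -> %s (%d non-missing calls vs %d / %d)\n",
            utils::tail(merged$samples, 1),
            sum(!is.na(merged$calls[nrow(merged$calls), ])),
            sum(!is.na(g$calls["F3", ])), sum(!is.na(g$calls["dupA", ]))))
cat("Wrote results/kinship_classes.tsv\n")
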