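#!/usr/bin/env Rscript
# f-statistics on simulated groups: a cladality screen for a true clade
# and for a pair broken by admixture, plus the chrX-versus-autosome
# outgroup-f3 contrast under male-biased steppe admixture.

suppressPackageStartupMessages(library(ancientpop))
dir.create("results", showWarnings = FALSE)
seed <- 202

specs <- c(list(pop_spec("out", f = 0.4),
                pop_spec("anc_ab", f = 0.1),
                pop_spec("A",  f = 0.02, parent = "anc_ab"),
                pop_spec("B",  f = 0.02, parent = "anc_ab"),
                pop_spec("intr", f = 0.15),
                pop_spec("t1", f = 0.02, parent = "intr"),
                pop_spec("Badm", f = 0.005, admix = c(B = 0.7, intr = 0.3))),
           lapply(2:8, function(k) pop_spec(paste0("t", k), f = 0.08)))
tr <- simulate_frequencies(20000, specs, seed = seed)
pops <- rownames(tr$freq_auto)
g <- sample_genotypes(tr, setNames(rep(5, length(pops)), pops),
                      missing_rate = 0.1, seed = seed + 1)
fr <- group_allele_frequencies(g)

clade <- cladality_test(fr, "A", "B", paste0("t", 1:8), "out")
broken <- cladality_test(fr, "A", "Badm", paste0("t", 1:8), "out")
cat(sprintf("True clade (A,B): %.0f%% of panel |Z|<=3 -> %s\n",
            100 * clade$fraction_nonsig,
            if (clade$cladal) "cladal" else "noncladal"))
cat(sprintf("Admixed pair (A, B+30%% intrusive): %.0f%% |Z|<=3 -> %s; significant: %s\n",
            100 * broken$fraction_nonsig,
            if (broken$cladal) "cladal" else "noncladal",
            paste(broken$significant$panel_group, collapse = ", ")))
out <- rbind(cbind(pair = "A,B", clade$table),
             cbind(pair = "A,Badm", broken$table))
write.table(out, "results/fstats_cladality.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# sex-biased admixture: steppe males x farmer females
specs_x <- c(list(pop_spec("out", f = 0.4),
                  pop_spec("steppe", f = 0.1),
                  pop_spec("farmer", f = 0.1),
                  pop_spec("steppe_ref", f = 0.02, parent = "steppe"),
                  pop_spec("farmer_ref", f = 0.02, parent = "farmer"),
                  pop_spec("adm", f = 0.005,
                           male_w = c(steppe = 0.9, farmer = 0.1),
                           female_w = c(steppe = 0.1, farmer = 0.9))),
             lapply(1:3, function(k) pop_spec(paste0("t", k), f = 0.15)))
trx <- simulate_frequencies(15000, specs_x, seed = seed + 2)
contrast <- chrx_autosome_contrast(as_group_freqs(trx$freq_auto),
                                   as_group_freqs(trx$freq_x),
                                   "out", "adm",
                                   c("steppe_ref", "farmer_ref",
                                     paste0("t", 1:3)))
write.table(contrast, "results/fstats_chrx_contrast.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("chrX-autosome contrast D: farmer-side %+0.2f, steppe-side %+0.2f (female-biased source attracts on chrX)\n",
            contrast$d[contrast$panel_group == "farmer_ref"],
            contrast$d[contrast$panel_group == "steppe_ref"]))
cat("Wrote results/fstats_cladality.tsv, results/fstats_chrx_contrast.tsv\n")
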