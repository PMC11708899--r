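#!/usr/bin/env Rscript
# PCA projection and the geographically matched heterogeneity test: a
# study set mixing two diverged populations is compared against matched
# single-population reference subsets of equal geographic concentration.

suppressPackageStartupMessages(library(ancientpop))
dir.create("results", showWarnings = FALSE)
seed <- 404

specs <- list(pop_spec("P1", f = 0.1), pop_spec("P2", f = 0.1))
tr <- simulate_frequencies(4000, specs, seed = seed)
ref <- sample_genotypes(tr, c(P1 = 30, P2 = 30), mode = "diploid",
                        seed = seed + 1)
model <- fit_pca(ref, 10)
cat(sprintf("PCA: %d components, leading eigenvalues %s\n",
            model$n_components,
            paste(sprintf("%.1f", model$eigenvalues[1:3]), collapse = ", ")))

study <- sample_genotypes(tr, c(P1 = 6, P2 = 6), missing_rate = 0.5,
                          seed = seed + 2)
study$samples <- paste0("st_", study$samples)
rownames(study$calls) <- study$samples
panel <- sample_genotypes(tr, c(P1 = 40), missing_rate = 0.3, seed = seed + 3)
panel$samples <- paste0("rf_", panel$samples)
rownames(panel$calls) <- panel$samples

sc_study <- scaled_coordinate_matrix(model, project_lsq(model, study), 10)
sc_panel <- scaled_coordinate_matrix(model, project_lsq(model, panel), 10)
write.table(data.frame(id = rownames(sc_study), round(sc_study, 4)),
            "results/pca_scores_study.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

geo <- simulate_geo_dates(40, center = c(49, 32), radius_km = 300,
                          seed = seed + 4)
geo$id <- rownames(sc_panel)
subs <- matched_subsets(geo, radius_km = 250, min_size = 10, seed = seed + 5)
dsets <- lapply(subs, function(s) pairwise_distance_set(sc_panel, s$members,
                                                        s$seed))
study_set <- pairwise_distance_set(sc_study, rownames(sc_study), "study")
rep_ <- heterogeneity_report(study_set, dsets)
print(rep_)
write.table(data.frame(set = c("study", vapply(dsets, `[[`, "", "label")),
                       mean_distance = c(rep_$study_mean, rep_$subset_means),
                       n_distances = c(length(study_set$distances),
                                       vapply(dsets, function(d)
                                         length(d$distances), 0L))),
            "results/heterogeneity_means.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/pca_scores_study.tsv, results/heterogeneity_means.tsv\n")
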