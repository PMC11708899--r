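#' Cohort summary and end-to-end pipeline driver
#'
#' @name pipeline
NULL

#' Cohort summary report: date bins, sexes, coverage
#'
#' Summarises a sample-metadata table the way cohort papers report it:
#' date-bin membership counts (by range midpoint, after the stated
#' exclusions), the genetic-sex tally, and cumulative coverage counts at a
#' set of thresholds, plus the pairwise-distance set size `n(n-1)/2`
#' implied by each bin.
#'
#' @param metadata metadata data frame (see [read_sample_metadata()]).
#' @param bins date bins (default [default_date_bins()]).
#' @param exclusions ids excluded from binning.
#' @param coverage_thresholds cumulative coverage cutoffs.
#' @return List `n`, `bin_counts`, `pair_counts`, `sex`, `coverage_counts`.
#' @export
table1_report <- function(metadata, bins = default_date_bins(),
                          exclusions = character(0),
                          coverage_thresholds = c(0.3, 0.5, 1.0)) {
  if (!nrow(metadata)) {
    return(list(n = 0L,
                bin_counts = stats::setNames(rep(0L, nrow(bins)), bins$name),
                pair_counts = stats::setNames(rep(0L, nrow(bins)), bins$name),
                sex = c(n_xx = 0L, n_xy = 0L, n_unknown = 0L),
                coverage_counts = stats::setNames(
                  rep(0L, length(coverage_thresholds)),
                  paste0(">", coverage_thresholds))))
  }
  binning <- assign_date_bins(metadata, bins, exclusions)
  counts <- binning$counts
  cov_counts <- vapply(coverage_thresholds, function(t)
    sum(metadata$coverage > t, na.rm = TRUE), 0L)
  list(n = nrow(metadata),
       bin_counts = counts,
       pair_counts = counts * (counts - 1L) / 2L,
       sex = sex_tally(metadata),
       coverage_counts = stats::setNames(cov_counts,
                                         paste0(">", coverage_thresholds)),
       unassigned = binning$unassigned,
       excluded = binning$excluded)
}

.child_seed <- function(seed, offset) (seed * 1000L + offset) %% 2147483647L

#' Run a configured end-to-end synthetic analysis
#'
#' Executes the requested stages in dependency order from one declarative
#' configuration: simulate a cohort with known truth, apply sample QC, fit
#' PCA and project, run the heterogeneity comparison, kinship and sexing.
#' Each stage derives its seed deterministically from the global seed, so
#' partial reruns reproduce full-run results. All tables are written as
#' TSV under `out_dir` together with a JSON provenance record of the
#' resolved configuration.
#'
#' @param config a named list, or the path to a YAML file with blocks
#'   `seed`, `simulation` (`n_snps`, `pop_f`, `samples_per_pop`,
#'   `missing_rate`), optional `qc` (`min_snps`), `pca` (`n_components`,
#'   `k`), `sexing` (`n_individuals`, `total_reads`).
#' @param out_dir output directory (created).
#' @return Invisibly, a list with the stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (block in c("seed", "simulation"))
    if (is.null(config[[block]])) stop("config is missing the '", block, "' block")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  sim <- config$simulation
  specs <- list(pop_spec("popA", f = sim$pop_f %||% 0.05),
                pop_spec("popB", f = sim$pop_f %||% 0.05))
  truth <- simulate_frequencies(sim$n_snps, specs, seed = .child_seed(seed, 1))
  spp <- unlist(sim$samples_per_pop %||% list(popA = 10, popB = 10))
  mat <- sample_genotypes(truth, spp, missing_rate = sim$missing_rate %||% 0.1,
                          seed = .child_seed(seed, 2))
  if (!is.null(config$qc))
    mat <- filter_samples_by_snp_overlap(mat, config$qc$min_snps)
  pca_cfg <- config$pca %||% list()
  n_comp <- pca_cfg$n_components %||% 5
  model <- fit_pca(mat, n_comp)
  proj <- project_lsq(model, mat)
  k <- min(pca_cfg$k %||% n_comp, n_comp)
  coords <- scaled_coordinate_matrix(model, proj, k)
  utils::write.table(
    data.frame(id = rownames(coords), coords, check.names = FALSE),
    file.path(out_dir, "scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  groups <- attr(mat, "group")[mat$samples]
  freqs <- group_allele_frequencies(mat, groups)
  fres <- f3(freqs, rownames(freqs$freq)[1], rownames(freqs$freq)[1],
             rownames(freqs$freq)[2])
  sx_cfg <- config$sexing %||% list(n_individuals = 20, total_reads = 10000)
  truth_sex <- rep(c("XX", "XY"), length.out = sx_cfg$n_individuals)
  rc <- simulate_read_counts(truth_sex, sx_cfg$total_reads,
                             seed = .child_seed(seed, 3))
  sexes <- cbind(rc["true_sex"], assign_sex(rc$n_x, rc$n_y))
  utils::write.table(sexes, file.path(out_dir, "sexing.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  provenance <- list(package_version = as.character(utils::packageVersion("ancientpop")),
                     seed = seed, config = config)
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(truth = truth, matrix = mat, model = model,
                 scores = coords, f3 = fres, sexing = sexes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
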