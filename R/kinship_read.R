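#' READ-style kinship from pseudo-haploid mismatch rates
#'
#' For each pair of pseudo-haploid samples, the mismatch rate P0 (fraction
#' of co-observed sites with different calls) is computed in windows of
#' physical coordinates. Because P0 depends on panel diversity and
#' coverage, scores are normalised by the cohort median of per-pair mean
#' P0 -- the expected value for an unrelated pair when most pairs in the
#' cohort are unrelated. Normalised scores classify pairs: below 0.625
#' identical/twin, below 0.8125 first degree, below 0.90625 second degree,
#' otherwise unrelated (the thresholds halve the expected allele-sharing
#' deficit degree by degree).
#'
#' @name kinship_read
NULL

#' Select sites by minor allele frequency for kinship analysis
#'
#' @param panel_freqs numeric vector of panel allele frequencies per SNP
#'   (truth frequencies in synthetic use, or a reference-panel estimate).
#' @param min_maf minimum minor allele frequency (default 0.1, exclusive).
#' @return Integer vector of selected site indices.
#' @export
select_kinship_sites <- function(panel_freqs, min_maf = 0.1) {
  maf <- pmin(panel_freqs, 1 - panel_freqs)
  sel <- which(maf > min_maf)
  if (!length(sel)) stop("no site passes the MAF filter")
  sel
}

#' Windowed pairwise mismatch rates (P0)
#'
#' @param mat a pseudo-haploid [geno_matrix()].
#' @param sites site indices to use (e.g. from [select_kinship_sites()]).
#' @param window_span window width in bp of physical position (default
#'   1 Mb).
#' @param min_sites minimum co-observed sites for a window to count
#'   (default 10).
#' @return A `p0_windows` list: per pair, a data frame (`window`,
#'   `n_sites`, `p0`); pairs with no usable window carry a zero-row frame.
#' @export
pairwise_p0 <- function(mat, sites = seq_len(ncol(mat$calls)),
                        window_span = 1e6, min_sites = 10) {
  stopifnot(inherits(mat, "geno_matrix"))
  if (any(mat$ploidy != "pseudohaploid"))
    stop("P0 is defined on pseudo-haploid calls")
  calls <- mat$calls[, sites, drop = FALSE]
  snp <- mat$snps[sites, , drop = FALSE]
  win <- paste(snp$chrom, floor(snp$pos / window_span), sep = ":")
  ids <- mat$samples
  n <- length(ids)
  if (n < 2) stop("need at least two samples")
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      both <- !is.na(calls[i, ]) & !is.na(calls[j, ])
      mm <- both & (calls[i, ] != calls[j, ])
      n_w <- rowsum(as.numeric(both), win)
      mm_w <- rowsum(as.numeric(mm), win)
      keep <- n_w[, 1] >= min_sites
      out[[paste(ids[i], ids[j], sep = "|")]] <-
        data.frame(window = rownames(n_w)[keep],
                   n_sites = n_w[keep, 1],
                   p0 = mm_w[keep, 1] / n_w[keep, 1],
                   row.names = NULL)
    }
  }
  structure(out, class = "p0_windows")
}

#' Classify pairwise relatedness from windowed P0
#'
#' Each pair's score is the mean window P0; the cohort normalisation value
#' is the median of these means (assumed-unrelated baseline, robust to a
#' few relatives). Classes follow fixed thresholds on the normalised
#' score. Pairs without usable windows are flagged `no_data`. If the
#' cohort is degenerate (median zero or all scores equal, so no unrelated
#' baseline exists), classification is suppressed with a warning.
#'
#' @param p0 a `p0_windows` object.
#' @param thresholds named vector with `identical`, `first`, `second`
#'   upper bounds on the normalised score.
#' @return Data frame (`id1`, `id2`, `mean_p0`, `norm_p0`, `se_norm`,
#'   `class`, `n_windows`, `n_sites`).
#' @export
classify_kinship <- function(p0, thresholds = c(identical = 0.625,
                                                first = 0.8125,
                                                second = 0.90625)) {
  if (length(p0) < 2) stop("normalisation needs at least two pairs")
  pairs <- strsplit(names(p0), "|", fixed = TRUE)
  mean_p0 <- vapply(p0, function(w) if (nrow(w)) mean(w$p0) else NA_real_, 0)
  se_p0 <- vapply(p0, function(w)
    if (nrow(w) > 1) stats::sd(w$p0) / sqrt(nrow(w)) else NA_real_, 0)
  norm_val <- stats::median(mean_p0, na.rm = TRUE)
  degenerate <- !is.finite(norm_val) || norm_val <= 0 ||
    isTRUE(all(abs(mean_p0 - mean_p0[1]) < 1e-12))
  if (degenerate) {
    warning("degenerate cohort: no unrelated baseline; classification suppressed")
    norm <- rep(NA_real_, length(mean_p0))
  } else {
    norm <- mean_p0 / norm_val
  }
  cls <- rep(NA_character_, length(norm))
  cls[!is.na(norm)] <- "unrelated"
  cls[!is.na(norm) & norm < thresholds["second"]] <- "second_degree"
  cls[!is.na(norm) & norm < thresholds["first"]] <- "first_degree"
  cls[!is.na(norm) & norm < thresholds["identical"]] <- "identical_twin"
  cls[is.na(mean_p0)] <- "no_data"
  data.frame(id1 = vapply(pairs, `[`, "", 1),
             id2 = vapply(pairs, `[`, "", 2),
             mean_p0 = mean_p0,
             norm_p0 = norm,
             se_norm = if (degenerate) NA_real_ else se_p0 / norm_val,
             class = cls,
             n_windows = vapply(p0, nrow, 0L),
             n_sites = vapply(p0, function(w) sum(w$n_sites), 0),
             row.names = NULL)
}

#' Merge two genetically identical samples
#'
#' Produces one consensus pseudo-haploid sample: calls agreeing in both
#' copies are kept, conflicting calls become missing, and a call observed
#' in only one copy is kept.
#'
#' @param mat a [geno_matrix()].
#' @param pair character vector of the two sample ids.
#' @param kinship optional classification table from [classify_kinship()];
#'   unless `force = TRUE`, the pair must be classed `identical_twin`.
#' @param new_id identifier of the merged sample (default the two ids
#'   joined).
#' @param force merge without a supporting classification.
#' @return A `geno_matrix` with the pair replaced by the merged sample.
#' @export
merge_identical <- function(mat, pair, kinship = NULL, new_id = NULL,
                            force = FALSE) {
  stopifnot(length(pair) == 2, all(pair %in% mat$samples))
  if (!force) {
    if (is.null(kinship)) stop("provide a kinship classification or force = TRUE")
    hit <- (kinship$id1 %in% pair) & (kinship$id2 %in% pair)
    if (!any(hit) || kinship$class[hit][1] != "identical_twin")
      stop("pair is not classified identical_twin (use force = TRUE to override)")
  }
  i <- match(pair[1], mat$samples); j <- match(pair[2], mat$samples)
  a <- mat$calls[i, ]; b <- mat$calls[j, ]
  merged <- ifelse(is.na(a), b, ifelse(is.na(b), a,
                   ifelse(a == b, a, NA_integer_)))
  keep <- setdiff(seq_along(mat$samples), c(i, j))
  if (is.null(new_id)) new_id <- paste0(pair[1], pair[2])
  geno_matrix(rbind(mat$calls[keep, , drop = FALSE], merged),
              mat$snps,
              c(mat$samples[keep], new_id),
              c(mat$ploidy[keep], "pseudohaploid"))
}
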