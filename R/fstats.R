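#' f-statistics with block-jackknife standard errors
#'
#' f4(A,B;C,D) is the average over SNPs of (a-b)(c-d) in allele
#' frequencies; it has zero expectation when (A,B) and (C,D) form disjoint
#' clades. The outgroup f3(O;A,B), the average of (o-a)(o-b), measures
#' shared drift of A and B since their divergence from a distant outgroup.
#' Standard errors come from a weighted delete-one-block jackknife over
#' contiguous SNP blocks, which is robust to local linkage.
#'
#' No small-sample bias correction is applied to f3/f4: the frequency
#' cross-products are unbiased in the population frequencies, and
#' heterozygosity-based corrections are ill-defined for pseudo-haploid
#' groups where each sample contributes a single allele observation.
#'
#' @name fstats
NULL

#' Per-group allele frequencies and observation counts
#'
#' A pseudo-haploid sample contributes one observed allele per covered SNP,
#' a diploid sample two. The group frequency is (sum of alt-allele
#' observations) / (total observed alleles); it is `NA` where a group has
#' no data.
#'
#' @param mat a [geno_matrix()].
#' @param groups named character vector or data frame (`id`, `group`)
#'   assigning samples to groups; unassigned samples are ignored.
#' @return A `group_freqs` list: `freq` and `count` (group x SNP matrices),
#'   `n_samples`, and the SNP registry.
#' @export
group_allele_frequencies <- function(mat, groups = attr(mat, "group")) {
  stopifnot(inherits(mat, "geno_matrix"))
  if (is.data.frame(groups)) groups <- stats::setNames(groups$group, groups$id)
  if (is.null(names(groups))) stop("groups must be named by sample id")
  assign <- groups[mat$samples]
  keep <- !is.na(assign)
  if (!any(keep)) stop("no sample is assigned to a group")
  calls <- mat$calls[keep, , drop = FALSE]
  grp <- as.character(assign[keep])
  ploidy_w <- ifelse(mat$ploidy[keep] == "diploid", 2L, 1L)
  obs <- (!is.na(calls)) * ploidy_w          # allele observations per call
  alt <- calls
  alt[is.na(alt)] <- 0L
  # alt-allele observations: dosage for diploid, dosage/2 for pseudo-haploid
  alt <- alt * ifelse(mat$ploidy[keep] == "diploid", 1, 0.5)
  count <- rowsum(obs, grp)
  alt_sum <- rowsum(alt, grp)
  freq <- alt_sum / count
  freq[count == 0] <- NA_real_
  n_samples <- table(grp)
  if (any(n_samples == 0)) stop("empty group")
  structure(list(freq = freq, count = count,
                 n_samples = as.integer(n_samples[rownames(freq)]),
                 snps = mat$snps),
            class = "group_freqs")
}

#' Build a group_freqs object directly from frequency matrices
#'
#' Useful for analyses at the population-frequency level (e.g. simulated
#' truth), where every SNP counts as observed with a nominal allele count.
#'
#' @param freq population x SNP frequency matrix.
#' @param count observation count (scalar or matrix).
#' @param snps optional SNP registry.
#' @return A `group_freqs` list.
#' @export
as_group_freqs <- function(freq, count = 2, snps = NULL) {
  freq <- as.matrix(freq)
  if (length(count) == 1)
    count <- matrix(count, nrow(freq), ncol(freq), dimnames = dimnames(freq))
  if (is.null(snps)) snps <- .default_snp_registry(ncol(freq))
  structure(list(freq = freq, count = count,
                 n_samples = rep(NA_integer_, nrow(freq)), snps = snps),
            class = "group_freqs")
}

#' Contiguous SNP blocks for the jackknife
#'
#' Blocks are runs of `block_size` consecutive SNPs in map order, indexed on
#' the full SNP registry so that the same SNP always falls in the same
#' block regardless of which statistic uses it.
#'
#' @param n_snps total number of SNPs.
#' @param block_size SNPs per block (default 500).
#' @return Integer vector of block ids, length `n_snps`.
#' @export
make_blocks <- function(n_snps, block_size = 500) {
  (seq_len(n_snps) - 1L) %/% as.integer(block_size) + 1L
}

#' Weighted delete-one-block jackknife for a mean
#'
#' The point estimate is the plain mean over all values. The standard error
#' uses the weighted jackknife for unequal block sizes (Busing et al.'s
#' formulation), which reduces to the textbook delete-one jackknife when
#' all blocks hold the same number of SNPs.
#'
#' @param values numeric vector of per-SNP contributions.
#' @param blocks block id per value.
#' @return List `estimate`, `se`, `n_blocks`.
#' @export
block_jackknife <- function(values, blocks) {
  ok <- !is.na(values)
  values <- values[ok]; blocks <- blocks[ok]
  n <- length(values)
  sums <- rowsum(values, blocks)
  m <- rowsum(rep(1, n), blocks)[, 1]
  g <- length(m)
  if (g < 2) stop("block jackknife needs at least 2 non-empty blocks")
  total <- sum(values)
  est <- total / n
  loo <- (total - sums[, 1]) / (n - m)       # delete-one-block means
  h <- n / m
  theta_j <- g * est - sum((1 - m / n) * loo)
  tau <- h * est - (h - 1) * loo             # pseudo-values
  var_j <- sum((tau - theta_j)^2 / (h - 1)) / g
  list(estimate = est, se = sqrt(var_j), n_blocks = g)
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g +/- %.3g (Z = %.2f, %d SNPs, %d blocks)\n",
              x$stat, paste(x$pops, collapse = ", "),
              x$estimate, x$se, x$z, x$n_snps, x$n_blocks))
  invisible(x)
}

.freq_rows <- function(freqs, groups) {
  missing <- setdiff(groups, rownames(freqs$freq))
  if (length(missing))
    stop("group(s) not present in frequencies: ", paste(missing, collapse = ", "))
  freqs$freq[groups, , drop = FALSE]
}

#' f4 statistic with block-jackknife SE
#'
#' Estimate over the SNPs observed in all four groups of the mean of
#' `(a - b)(c - d)`.
#'
#' @param freqs a `group_freqs` object.
#' @param a,b,c_,d group labels (the statistic is f4(a, b; c_, d)).
#' @param block_size jackknife block size in SNPs.
#' @return An `fstat_result`.
#' @export
f4 <- function(freqs, a, b, c_, d, block_size = 500) {
  fm <- .freq_rows(freqs, c(a, b, c_, d))
  used <- which(colSums(is.na(fm)) == 0)
  v <- (fm[1, used] - fm[2, used]) * (fm[3, used] - fm[4, used])
  blocks <- make_blocks(ncol(fm), block_size)[used]
  .fstat_with_blocks(v, blocks, "f4", c(a, b, c_, d), block_size)
}

.fstat_with_blocks <- function(per_snp, blocks, label, pops, block_size) {
  n_used <- length(per_snp)
  if (n_used == 0) stop("no SNP is observed in all groups of ", label)
  n_blocks <- length(unique(blocks))
  if (n_blocks < 2) {
    res <- list(estimate = mean(per_snp), se = NA_real_, n_blocks = n_blocks)
    flag <- "se_unavailable"
  } else {
    res <- block_jackknife(per_snp, blocks)
    flag <- NA_character_
  }
  z <- if (!is.na(res$se) && res$se == 0 && res$estimate == 0) 0
       else res$estimate / res$se
  structure(list(stat = label, pops = pops, estimate = res$estimate,
                 se = res$se, z = z,
                 n_snps = n_used, n_blocks = res$n_blocks,
                 block_size = block_size, flag = flag),
            class = "fstat_result")
}

#' Outgroup f3 statistic with block-jackknife SE
#'
#' Estimate over complete-case SNPs of the mean of `(o - a)(o - b)`,
#' measuring shared drift of `a` and `b` relative to outgroup `o`.
#'
#' @inheritParams f4
#' @param o outgroup label.
#' @return An `fstat_result`.
#' @export
f3 <- function(freqs, o, a, b, block_size = 500) {
  fm <- .freq_rows(freqs, c(o, a, b))
  used <- which(colSums(is.na(fm)) == 0)
  v <- (fm[1, used] - fm[2, used]) * (fm[1, used] - fm[3, used])
  blocks <- make_blocks(ncol(fm), block_size)[used]
  .fstat_with_blocks(v, blocks, "f3", c(o, a, b), block_size)
}

#' Cladality screen for a pair of groups
#'
#' Runs f4(outgroup, T; A, B) for every panel group T. The pair is judged
#' cladal when at least `min_fraction` of the panel yields |Z| <=
#' `z_threshold` (i.e. no panel group is significantly closer to one of A,
#' B than to the other).
#'
#' @param freqs `group_freqs`.
#' @param a,b the group pair under test.
#' @param panel character vector of comparison groups (must exclude `a`,
#'   `b` and `outgroup`).
#' @param outgroup distant outgroup label.
#' @param block_size jackknife block size.
#' @param z_threshold |Z| defining a significant f4 (default 3).
#' @param min_fraction fraction of non-significant panel results required
#'   for a cladal verdict (default 0.95).
#' @return A `cladality_result` list with the per-panel table, the fraction
#'   of |Z| <= threshold, the verdict, and the significant groups with the
#'   sign of their attraction.
#' @export
cladality_test <- function(freqs, a, b, panel, outgroup, block_size = 500,
                           z_threshold = 3, min_fraction = 0.95) {
  panel <- setdiff(panel, c(a, b, outgroup))
  if (!length(panel)) stop("empty comparison panel")
  rows <- lapply(panel, function(t_grp) {
    r <- f4(freqs, outgroup, t_grp, a, b, block_size)
    data.frame(panel_group = t_grp, estimate = r$estimate, se = r$se,
               z = r$z, n_snps = r$n_snps, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  zok <- abs(tab$z) <= z_threshold
  frac <- mean(zok, na.rm = TRUE)
  sig <- tab[!is.na(tab$z) & !zok, , drop = FALSE]
  structure(list(pair = c(a, b), table = tab, fraction_nonsig = frac,
                 cladal = frac >= min_fraction,
                 significant = data.frame(panel_group = sig$panel_group,
                                          sign = sign(sig$z), z = sig$z),
                 z_threshold = z_threshold, min_fraction = min_fraction),
            class = "cladality_result")
}

#' @export
print.cladality_result <- function(x, ...) {
  cat(sprintf("cladality(%s, %s): %.1f%% of %d panel groups with |Z| <= %g -> %s\n",
              x$pair[1], x$pair[2], 100 * x$fraction_nonsig, nrow(x$table),
              x$z_threshold, if (x$cladal) "cladal" else "noncladal"))
  invisible(x)
}

#' chrX versus autosome outgroup-f3 contrast
#'
#' Computes outgroup f3(outgroup; focal, T) for each panel group T on the
#' autosomal and the chrX frequency tracks, drops panel entries with fewer
#' than `min_snps_x` usable chrX SNPs, standardises each f3 vector across
#' the panel, and reports the difference `D = z_X - z_auto`. A positive D
#' marks a group with relatively more affinity to the focal group through
#' female ancestors (chrX carries about two-thirds female ancestry).
#'
#' @param freqs_auto,freqs_x `group_freqs` for the two tracks.
#' @param outgroup,focal group labels.
#' @param panel comparison groups.
#' @param min_snps_x minimum usable chrX SNPs per panel entry (default
#'   1000).
#' @param block_size jackknife block size.
#' @return Data frame (`panel_group`, `f3_auto`, `f3_x`, `n_snps_x`,
#'   `z_auto`, `z_x`, `d`).
#' @export
chrx_autosome_contrast <- function(freqs_auto, freqs_x, outgroup, focal, panel,
                                   min_snps_x = 1000, block_size = 500) {
  panel <- setdiff(panel, c(outgroup, focal))
  rows <- lapply(panel, function(t_grp) {
    ra <- f3(freqs_auto, outgroup, focal, t_grp, block_size)
    rx <- f3(freqs_x, outgroup, focal, t_grp, block_size)
    data.frame(panel_group = t_grp, f3_auto = ra$estimate, f3_x = rx$estimate,
               n_snps_auto = ra$n_snps, n_snps_x = rx$n_snps,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$n_snps_x >= min_snps_x, , drop = FALSE]
  if (!nrow(tab)) stop("all panel entries fall below the chrX SNP threshold")
  zs <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }
  tab$z_auto <- zs(tab$f3_auto)
  tab$z_x <- zs(tab$f3_x)
  tab$d <- tab$z_x - tab$z_auto
  tab
}
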