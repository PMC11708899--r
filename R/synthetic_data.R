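#' Synthetic-data generators with known ground truth
#'
#' Every input the analysis pipeline consumes can be simulated: population
#' allele frequencies under Balding-Nichols drift, admixed populations
#' (optionally with sex-biased contributions, giving distinct autosomal and
#' chrX weights), diploid or pseudo-haploid genotype matrices with
#' missingness, pedigrees with relatives and duplicated samples, X/Y read
#' counts, chrY call tables, and spatially clustered dated reference panels.
#' All generators are pure functions of their arguments and `seed`.
#'
#' @name synthetic_data
NULL

.drift_eps <- 1e-7  # below this F, drift is treated as exactly zero

#' Describe a simulated population
#'
#' @param name population label.
#' @param f Balding-Nichols drift parameter (Fst-like) in `[0, 1)`; values
#'   below 1e-7 mean no drift.
#' @param parent name of the parent population (default the shared ancestral
#'   frequency), ignored when `admix` is given.
#' @param admix optional admixture specification: a named numeric vector of
#'   source weights summing to 1. The population's pre-drift frequency is
#'   the weighted mean of its sources.
#' @param male_w,female_w optional named weight vectors describing sex-biased
#'   contributions of the `admix` sources; see
#'   [sex_biased_weights()]. When supplied, `admix` may be omitted.
#' @return A `pop_spec` list.
#' @export
pop_spec <- function(name, f = 0, parent = "ANC", admix = NULL,
                     male_w = NULL, female_w = NULL) {
  if (f < 0 || f >= 1) stop("drift parameter f must be in [0, 1)")
  if (!is.null(male_w) || !is.null(female_w)) {
    if (is.null(male_w) || is.null(female_w))
      stop("both male_w and female_w are required for sex-biased admixture")
    w <- sex_biased_weights(male_w, female_w)
    admix <- w$auto
    admix_x <- w$x
  } else {
    admix_x <- admix
  }
  if (!is.null(admix)) {
    if (is.null(names(admix)) || abs(sum(admix) - 1) > 1e-8)
      stop("admixture weights must be named and sum to 1")
  }
  structure(list(name = name, f = f, parent = parent,
                 admix = admix, admix_x = admix_x),
            class = "pop_spec")
}

#' Autosomal and chrX admixture weights under sex-biased gene flow
#'
#' Autosomes are inherited equally from both parents, whereas two-thirds of
#' chrX ancestry traces through females. If source `i` contributes a
#' fraction `m_i` of male-side and `f_i` of female-side ancestry, its
#' autosomal weight is `(m_i + f_i) / 2` and its chrX weight
#' `(m_i + 2 f_i) / 3`.
#'
#' @param male_w,female_w named weight vectors over the same sources, each
#'   summing to 1.
#' @return List with components `auto` and `x`.
#' @export
sex_biased_weights <- function(male_w, female_w) {
  if (!identical(sort(names(male_w)), sort(names(female_w))))
    stop("male and female weights must cover the same sources")
  female_w <- female_w[names(male_w)]
  if (abs(sum(male_w) - 1) > 1e-8 || abs(sum(female_w) - 1) > 1e-8)
    stop("male and female weights must each sum to 1")
  list(auto = (male_w + female_w) / 2, x = (male_w + 2 * female_w) / 3)
}

.drift_draw <- function(p, f) {
  if (f < .drift_eps) return(p)
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  q <- stats::rbeta(length(p), a, b)
  pmin(pmax(q, 1e-9), 1 - 1e-9)
}

.build_track <- function(n_snps, specs, anc, x_track = FALSE) {
  freq <- matrix(NA_real_, nrow = length(specs), ncol = n_snps,
                 dimnames = list(vapply(specs, `[[`, "", "name"), NULL))
  for (sp in specs) {
    w <- if (x_track) sp$admix_x else sp$admix
    if (!is.null(w)) {
      miss <- setdiff(names(w), rownames(freq)[!is.na(freq[, 1])])
      if (length(miss))
        stop("admixture source(s) not yet defined: ", paste(miss, collapse = ", "))
      base <- drop(w %*% freq[names(w), , drop = FALSE])
    } else if (identical(sp$parent, "ANC")) {
      base <- anc
    } else {
      if (!(sp$parent %in% rownames(freq)) || anyNA(freq[sp$parent, 1]))
        stop("parent population not yet defined: ", sp$parent)
      base <- freq[sp$parent, ]
    }
    freq[sp$name, ] <- .drift_draw(base, sp$f)
  }
  freq
}

#' Simulate population allele frequencies under drift and admixture
#'
#' Ancestral frequencies are drawn from `ancestral_law` (default
#' Uniform(0.05, 0.95), mimicking a MAF-filtered SNP panel). Each
#' population's frequency is drawn per SNP from a Beta distribution with
#' mean equal to its parent's (or admixture-mean) frequency and
#' Balding-Nichols drift parameter `f`. The chrX track is an independent
#' set of frequencies built with the same topology but the chrX admixture
#' weights.
#'
#' @param n_snps number of autosomal SNPs.
#' @param pop_specs list of [pop_spec()] objects in dependency order.
#' @param seed integer RNG seed.
#' @param n_snps_x number of chrX SNPs (default `n_snps`).
#' @param ancestral_law function of `n` returning ancestral frequencies.
#' @return A `sim_truth` list: `freq_auto` and `freq_x` (population x SNP
#'   matrices), `anc_auto`, `anc_x`, `specs`, `seed`.
#' @export
simulate_frequencies <- function(n_snps, pop_specs, seed,
                                 n_snps_x = n_snps,
                                 ancestral_law = function(n) stats::runif(n, 0.05, 0.95)) {
  stopifnot(n_snps >= 1)
  if (inherits(pop_specs, "pop_spec")) pop_specs <- list(pop_specs)
  set.seed(seed)
  anc_a <- ancestral_law(n_snps)
  freq_a <- .build_track(n_snps, pop_specs, anc_a, x_track = FALSE)
  anc_x <- ancestral_law(n_snps_x)
  freq_x <- .build_track(n_snps_x, pop_specs, anc_x, x_track = TRUE)
  structure(list(freq_auto = freq_a, freq_x = freq_x,
                 anc_auto = anc_a, anc_x = anc_x,
                 specs = pop_specs, seed = seed),
            class = "sim_truth")
}

#' Autosomal and chrX frequency tracks for one sex-biased admixed population
#'
#' Convenience wrapper: given a [pop_spec()] carrying sex-biased weights and
#' the source populations' frequency tracks, returns the admixed
#' population's autosomal and chrX frequencies (drift applied with the
#' spec's `f`).
#'
#' @param spec a [pop_spec()] with sex-biased weights.
#' @param freq_auto,freq_x source frequency matrices (rows named by source).
#' @param seed integer RNG seed.
#' @return List with `auto` and `x` frequency vectors and the weight sets.
#' @export
simulate_sex_biased_admixture <- function(spec, freq_auto, freq_x, seed) {
  if (is.null(spec$admix) || is.null(spec$admix_x))
    stop("spec carries no admixture weights")
  set.seed(seed)
  base_a <- drop(spec$admix %*% freq_auto[names(spec$admix), , drop = FALSE])
  base_x <- drop(spec$admix_x %*% freq_x[names(spec$admix_x), , drop = FALSE])
  list(auto = .drift_draw(base_a, spec$f), x = .drift_draw(base_x, spec$f),
       w_auto = spec$admix, w_x = spec$admix_x)
}

.default_snp_registry <- function(n, chrom = "1", spacing = 1e4) {
  data.frame(id = sprintf("snp_%s_%d", chrom, seq_len(n)),
             chrom = chrom, gpos = NA_real_,
             pos = as.integer(seq_len(n) * spacing),
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

#' Sample genotype matrices from true frequencies
#'
#' Diploid calls are Binomial(2, p); pseudo-haploid calls are a single
#' Bernoulli(p) draw coded \{0, 2\}, emulating random-read haploid calling of
#' ancient samples. Missingness is applied independently per call.
#'
#' @param truth a `sim_truth` from [simulate_frequencies()], or a frequency
#'   matrix with populations in rows.
#' @param samples_per_pop named integer vector: samples to draw per
#'   population.
#' @param mode `"pseudohaploid"` (default) or `"diploid"`.
#' @param missing_rate per-call missingness probability in `[0, 1)`.
#' @param seed integer RNG seed.
#' @param track `"auto"` or `"x"`: which frequency track to sample.
#' @param spacing physical spacing (bp) between consecutive synthetic SNPs
#'   on the single pseudo-chromosome.
#' @return A [geno_matrix()]; the sample-to-population map is attached as
#'   attribute `group`.
#' @export
sample_genotypes <- function(truth, samples_per_pop, mode = "pseudohaploid",
                             missing_rate = 0, seed = 1, track = "auto",
                             spacing = 1e4) {
  stopifnot(mode %in% c("diploid", "pseudohaploid"),
            missing_rate >= 0, missing_rate < 1)
  freq <- if (inherits(truth, "sim_truth")) {
    if (track == "auto") truth$freq_auto else truth$freq_x
  } else as.matrix(truth)
  pops <- names(samples_per_pop)
  if (is.null(pops) || !all(pops %in% rownames(freq)))
    stop("samples_per_pop must be named by simulated populations")
  set.seed(seed)
  n_snps <- ncol(freq)
  ids <- unlist(lapply(pops, function(p)
    sprintf("%s_%d", p, seq_len(samples_per_pop[[p]]))))
  group <- rep(pops, times = unlist(samples_per_pop))
  n <- length(ids)
  p_mat <- freq[group, , drop = FALSE]
  calls <- if (mode == "diploid") {
    matrix(stats::rbinom(n * n_snps, 2L, as.vector(p_mat)), nrow = n)
  } else {
    matrix(2L * stats::rbinom(n * n_snps, 1L, as.vector(p_mat)), nrow = n)
  }
  if (missing_rate > 0)
    calls[matrix(stats::runif(n * n_snps) < missing_rate, nrow = n)] <- NA_integer_
  chrom <- if (track == "auto") "1" else "X"
  g <- geno_matrix(calls, .default_snp_registry(n_snps, chrom, spacing), ids,
                   if (mode == "diploid") "diploid" else "pseudohaploid")
  attr(g, "group") <- stats::setNames(group, ids)
  g
}

#' Simulate a pedigree of diploid genomes and their pseudo-haploid calls
#'
#' Founders are drawn from their population's frequencies; offspring inherit
#' one random allele per parent at every site; duplicate entries are
#' independent pseudo-haploid resamplings of a single underlying diploid
#' genome (emulating one individual sampled twice).
#'
#' @param truth `sim_truth` or frequency matrix (autosomal track used).
#' @param pedigree data frame with columns `id`, `pop` (founders), `father`,
#'   `mother` (NA for founders) and `duplicate_of` (NA unless the entry
#'   resamples another entry's genome).
#' @param mode `"pseudohaploid"` (default) or `"diploid"` output coding.
#' @param missing_rate per-call missingness probability.
#' @param seed integer RNG seed.
#' @param spacing physical SNP spacing in bp (window analyses assume
#'   physical positions).
#' @return A [geno_matrix()] with one sample per pedigree entry.
#' @export
simulate_pedigree <- function(truth, pedigree, mode = "pseudohaploid",
                              missing_rate = 0, seed = 1, spacing = 1e4) {
  freq <- if (inherits(truth, "sim_truth")) truth$freq_auto else as.matrix(truth)
  ped <- as.data.frame(pedigree)
  for (col in c("father", "mother", "duplicate_of"))
    if (is.null(ped[[col]])) ped[[col]] <- NA_character_
  set.seed(seed)
  n_snps <- ncol(freq)
  hap1 <- hap2 <- matrix(NA_integer_, nrow = nrow(ped), ncol = n_snps,
                         dimnames = list(ped$id, NULL))
  done <- character(0)
  remaining <- seq_len(nrow(ped))
  while (length(remaining)) {
    progressed <- FALSE
    for (i in remaining) {
      row <- ped[i, ]
      if (!is.na(row$duplicate_of)) {
        if (!(row$duplicate_of %in% done)) next
        hap1[i, ] <- hap1[row$duplicate_of, ]
        hap2[i, ] <- hap2[row$duplicate_of, ]
      } else if (!is.na(row$father) || !is.na(row$mother)) {
        if (is.na(row$father) || is.na(row$mother))
          stop("offspring ", row$id, " needs both parents")
        if (!all(c(row$father, row$mother) %in% done)) next
        pick_f <- stats::rbinom(n_snps, 1L, 0.5) == 1L
        pick_m <- stats::rbinom(n_snps, 1L, 0.5) == 1L
        hap1[i, ] <- ifelse(pick_f, hap1[row$father, ], hap2[row$father, ])
        hap2[i, ] <- ifelse(pick_m, hap1[row$mother, ], hap2[row$mother, ])
      } else {
        p <- freq[row$pop, ]
        hap1[i, ] <- stats::rbinom(n_snps, 1L, p)
        hap2[i, ] <- stats::rbinom(n_snps, 1L, p)
      }
      done <- c(done, row$id)
      remaining <- setdiff(remaining, i)
      progressed <- TRUE
    }
    if (!progressed)
      stop("pedigree is cyclic or references undefined entries: ",
           paste(ped$id[remaining], collapse = ", "))
  }
  calls <- if (mode == "diploid") {
    hap1 + hap2
  } else {
    pick <- matrix(stats::rbinom(length(hap1), 1L, 0.5) == 1L, nrow = nrow(hap1))
    2L * ifelse(pick, hap1, hap2)
  }
  if (missing_rate > 0)
    calls[matrix(stats::runif(length(calls)) < missing_rate,
                 nrow = nrow(calls))] <- NA_integer_
  g <- geno_matrix(calls, .default_snp_registry(n_snps, "1", spacing), ped$id,
                   if (mode == "diploid") "diploid" else "pseudohaploid")
  attr(g, "diploid_truth") <- hap1 + hap2
  g
}

#' Simulate X/Y read counts for genetic sexing
#'
#' The number of sex-chromosome reads mapping to chrY is Binomial with
#' success probability `q_male` for XY individuals and `q_female` (residual
#' mismapping) for XX individuals.
#'
#' @param true_sex character vector of `"XX"` / `"XY"`.
#' @param total total reads mapping to X or Y per individual (recycled).
#' @param seed integer RNG seed.
#' @param q_male,q_female expected chrY read fraction by sex.
#' @return Data frame with columns `true_sex`, `n_x`, `n_y`.
#' @export
simulate_read_counts <- function(true_sex, total, seed = 1,
                                 q_male = 0.25, q_female = 0.002) {
  stopifnot(all(total > 0), all(true_sex %in% c("XX", "XY")))
  set.seed(seed)
  total <- rep_len(total, length(true_sex))
  q <- ifelse(true_sex == "XY", q_male, q_female)
  n_y <- stats::rbinom(length(true_sex), total, q)
  data.frame(true_sex = true_sex, n_x = total - n_y, n_y = n_y)
}

#' A small Y-chromosome haplogroup tree
#'
#' @param tree data frame with columns `hg` and `parent` (`NA` for the root).
#' @return The validated tree with a `depth` column added.
#' @export
y_tree <- function(tree) {
  stopifnot(all(c("hg", "parent") %in% names(tree)))
  if (sum(is.na(tree$parent)) != 1) stop("tree must have exactly one root")
  depth <- stats::setNames(rep(NA_integer_, nrow(tree)), tree$hg)
  depth[is.na(tree$parent)] <- 0L
  while (anyNA(depth)) {
    ready <- is.na(depth[tree$hg]) & !is.na(depth[tree$parent])
    if (!any(ready)) stop("tree contains a cycle or orphan haplogroup")
    depth[tree$hg[ready]] <- depth[tree$parent[ready]] + 1L
  }
  tree$depth <- as.integer(depth[tree$hg])
  tree
}

.y_lineage <- function(tree, hg) {
  if (!(hg %in% tree$hg)) stop("unknown haplogroup: ", hg)
  lineage <- character(0)
  node <- hg
  while (!is.na(node)) {
    lineage <- c(lineage, node)
    node <- tree$parent[match(node, tree$hg)]
  }
  lineage
}

#' Simulate a chrY informative-position call table
#'
#' For a male carrying `true_hg`, positions on branches of the true lineage
#' (the haplogroup and its ancestors) are called derived with probability
#' `1 - flip_error`; off-lineage positions are derived with probability
#' `flip_error`. Each position is called at all with probability
#' `call_rate`. For a female (`true_hg = NA`), chrY coverage is spurious
#' (mismapped reads carrying the reference allele): positions are called
#' with probability `female_call_rate` and derived only at the flip-error
#' rate.
#'
#' @param tree haplogroup tree, see [y_tree()].
#' @param true_hg true haplogroup label, or `NA` for an XX individual.
#' @param n_positions_per_hg informative positions per branch (recycled over
#'   branches, or a named vector).
#' @param flip_error probability that a call has the wrong state.
#' @param seed integer RNG seed.
#' @param call_rate probability a position yields a call (male).
#' @param female_call_rate probability a position yields a (spurious) call
#'   for an XX individual; default 0.002, matching the residual chrY
#'   mismapping fraction used for read-count sexing.
#' @return Data frame (`hg`, `position`, `state`) of called positions only.
#' @export
simulate_y_calls <- function(tree, true_hg, n_positions_per_hg, flip_error,
                             seed = 1, call_rate = 1, female_call_rate = 0.002) {
  tree <- y_tree(tree)
  set.seed(seed)
  npos <- if (is.null(names(n_positions_per_hg)))
    stats::setNames(rep_len(n_positions_per_hg, nrow(tree)), tree$hg)
  else n_positions_per_hg[tree$hg]
  lineage <- if (is.na(true_hg)) character(0) else .y_lineage(tree, true_hg)
  rows <- lapply(tree$hg, function(hg) {
    n <- npos[[hg]]
    if (is.na(n) || n == 0) return(NULL)
    cr <- if (is.na(true_hg)) female_call_rate else call_rate
    called <- stats::runif(n) < cr
    if (!any(called)) return(NULL)
    n_called <- sum(called)
    p_derived <- if (is.na(true_hg)) flip_error
                 else if (hg %in% lineage) 1 - flip_error else flip_error
    state <- ifelse(stats::runif(n_called) < p_derived, "derived", "ancestral")
    data.frame(hg = hg, position = which(called), state = state,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(hg = character(0), position = integer(0),
                      state = character(0))
  attr(out, "tree") <- tree
  out
}

.deg2rad <- function(x) x * pi / 180

#' Simulate geographically clustered, dated reference metadata
#'
#' Points are drawn uniformly on a spherical cap of the given great-circle
#' radius around each cluster center; dates uniformly within the cluster's
#' window.
#'
#' @param n number of individuals (single-cluster form).
#' @param center `c(lat, lon)` in decimal degrees.
#' @param radius_km cap radius (great-circle km).
#' @param date_window `c(lo, hi)` signed years.
#' @param cluster_spec optional data frame (`lat`, `lon`, `radius_km`, `n`,
#'   `date_lo`, `date_hi`) describing several clusters; overrides the
#'   single-cluster arguments.
#' @param seed integer RNG seed.
#' @param prefix identifier prefix.
#' @return Metadata data frame (`id`, `group`, `lat`, `lon`, `date_lo`,
#'   `date_hi`, `date_mid`).
#' @export
simulate_geo_dates <- function(n, center = c(49, 32), radius_km = 500,
                               date_window = c(-700, -300), cluster_spec = NULL,
                               seed = 1, prefix = "ref") {
  set.seed(seed)
  if (is.null(cluster_spec))
    cluster_spec <- data.frame(lat = center[1], lon = center[2],
                               radius_km = radius_km, n = n,
                               date_lo = date_window[1], date_hi = date_window[2])
  out <- lapply(seq_len(nrow(cluster_spec)), function(k) {
    cl <- cluster_spec[k, ]
    stopifnot(cl$radius_km > 0)
    theta_max <- cl$radius_km / 6371.0
    # uniform on the cap: cos(theta) uniform on [cos(theta_max), 1]
    ct <- stats::runif(cl$n, cos(theta_max), 1)
    theta <- acos(pmin(pmax(ct, -1), 1))
    phi <- stats::runif(cl$n, 0, 2 * pi)
    lat0 <- .deg2rad(cl$lat); lon0 <- .deg2rad(cl$lon)
    lat <- asin(sin(lat0) * cos(theta) + cos(lat0) * sin(theta) * cos(phi))
    lon <- lon0 + atan2(sin(phi) * sin(theta) * cos(lat0),
                        cos(theta) - sin(lat0) * sin(lat))
    dates <- stats::runif(cl$n, cl$date_lo, cl$date_hi)
    data.frame(id = sprintf("%s%d_%d", prefix, k, seq_len(cl$n)),
               group = sprintf("%s%d", prefix, k),
               lat = lat * 180 / pi,
               lon = ((lon * 180 / pi + 180) %% 360) - 180,
               date_lo = dates, date_hi = dates, date_mid = dates)
  })
  do.call(rbind, out)
}
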