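# Independent oracles and small fixture builders used across the suite.
# These re-derive expected values by brute force or closed form and stay
# independent of the package code paths they check.

# textbook unweighted delete-one jackknife (valid for equal-size blocks)
brute_jackknife <- function(values, blocks) {
  ub <- unique(blocks)
  g <- length(ub)
  loo <- vapply(ub, function(b) mean(values[blocks != b]), 0)
  list(estimate = mean(values),
       se = sqrt((g - 1) / g * sum((loo - mean(loo))^2)))
}

# exhaustive minimal enclosing spherical cap over all 1-, 2- and 3-point
# circumscribing caps (caps have three degrees of freedom, so some support
# set of size <= 3 determines the optimum)
brute_min_cap_km <- function(lat, lon) {
  xyz <- cbind(cos(lat * pi / 180) * cos(lon * pi / 180),
               cos(lat * pi / 180) * sin(lon * pi / 180),
               sin(lat * pi / 180))
  n <- nrow(xyz)
  if (n == 1) return(0)
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  best <- Inf
  covers <- function(ax) {
    cosr <- min(xyz %*% ax)
    acos(min(1, max(-1, cosr)))
  }
  for (i in seq_len(n)) best <- min(best, covers(xyz[i, ]))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ax <- xyz[i, ] + xyz[j, ]
    nrm <- sqrt(sum(ax^2))
    if (nrm > 1e-12) best <- min(best, covers(ax / nrm))
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in seq(i + 1, n - 1)) for (k in seq(j + 1, n)) {
      ax <- cross3(xyz[j, ] - xyz[i, ], xyz[k, ] - xyz[i, ])
      nrm <- sqrt(sum(ax^2))
      if (nrm < 1e-12) next
      ax <- ax / nrm
      best <- min(best, covers(ax), covers(-ax))
    }
  }
  best * 6371.0
}

# point-in-convex-hull test in 2-D (hull from chull, counter-ordered)
in_hull_2d <- function(px, py, xs, ys) {
  h <- grDevices::chull(xs, ys)
  hx <- xs[h]; hy <- ys[h]
  m <- length(h)
  s <- vapply(seq_len(m), function(i) {
    j <- if (i == m) 1L else i + 1L
    (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
  }, 0)
  all(s <= 1e-12) || all(s >= -1e-12)
}

# exact expected pseudo-haploid mismatch rate by enumeration of
# genotype-pair probabilities at allele frequency p
enum_p0 <- function(p, relation = c("unrelated", "parent_offspring")) {
  relation <- match.arg(relation)
  gprob <- c(`0` = (1 - p)^2, `1` = 2 * p * (1 - p), `2` = p^2)
  # P(random read allele = alt | genotype)
  read_alt <- c(`0` = 0, `1` = 0.5, `2` = 1)
  pm <- 0
  for (g1 in 0:2) {
    for (g2 in 0:2) {
      joint <- if (relation == "unrelated") {
        gprob[[as.character(g1)]] * gprob[[as.character(g2)]]
      } else {
        # parent g1; offspring receives one parental allele + one from pool
        trans <- function(g1, g2) {
          p_from_parent <- c(`0` = 0, `1` = 0.5, `2` = 1)[[as.character(g1)]]
          pa <- c(1 - p_from_parent, p_from_parent)   # transmitted allele 0/1
          po <- c(1 - p, p)                           # other allele from pool
          sum(vapply(0:1, function(a) vapply(0:1, function(b)
            if (a + b == g2) pa[a + 1] * po[b + 1] else 0, 0), numeric(2)))
        }
        gprob[[as.character(g1)]] * trans(g1, g2)
      }
      a1 <- read_alt[[as.character(g1)]]
      a2 <- read_alt[[as.character(g2)]]
      pm <- pm + joint * (a1 * (1 - a2) + (1 - a1) * a2)
    }
  }
  pm
}

# Hudson-style Fst estimator (ratio of means) from two sampled frequency
# vectors with haploid sample sizes n1, n2
hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}

# tiny geno_matrix builder
toy_matrix <- function(calls, ploidy = "pseudohaploid", chrom = "1",
                       spacing = 1e4) {
  calls <- as.matrix(calls)
  snps <- data.frame(id = paste0("s", seq_len(ncol(calls))), chrom = chrom,
                     gpos = NA_real_,
                     pos = as.integer(seq_len(ncol(calls)) * spacing),
                     ref = "A", alt = "G")
  geno_matrix(calls, snps, paste0("ind", seq_len(nrow(calls))), ploidy)
}

# qpAdm recovery scenario: target = 0.6 A + 0.4 B, right populations
# differentially related to the sources through shared internal branches
recovery_specs <- function(w_a = 0.6) {
  c(list(
    pop_spec("P1", f = 0.05),
    pop_spec("P2", f = 0.05),
    pop_spec("A",  f = 0.05, parent = "P1"),
    pop_spec("R1", f = 0.05, parent = "P1"),
    pop_spec("B",  f = 0.05, parent = "P2"),
    pop_spec("R2", f = 0.05, parent = "P2"),
    pop_spec("T",  f = 0.01, admix = stats::setNames(c(w_a, 1 - w_a), c("A", "B")))),
    lapply(1:8, function(i) pop_spec(paste0("R", i + 2), f = 0.10 + 0.02 * i)))
}

recovery_freqs <- function(seed, n_snps = 50000, n_per_pop = 5,
                           missing_rate = 0.05) {
  tr <- simulate_frequencies(n_snps, recovery_specs(), seed = seed)
  pops <- setdiff(rownames(tr$freq_auto), c("P1", "P2"))
  g <- sample_genotypes(tr, stats::setNames(rep(n_per_pop, length(pops)), pops),
                        missing_rate = missing_rate, seed = seed + 1)
  group_allele_frequencies(g)
}

# admixture-cline reference panel: individuals vary along two admixture
# axes over three base populations, so the leading PCs carry genuine
# structure (as in continental human PCA) rather than pure sampling noise
cline_panel <- function(n_snps = 8000, n_ref = 60, seed = 1) {
  base <- list(pop_spec("Q1", f = 0.2), pop_spec("Q2", f = 0.2),
               pop_spec("Q3", f = 0.2))
  tr <- simulate_frequencies(n_snps, base, seed = seed)
  q <- tr$freq_auto
  set.seed(seed + 1)
  ab <- cbind(runif(n_ref, 0.05, 0.50), runif(n_ref, 0.05, 0.45))
  freqs <- t(apply(ab, 1, function(w)
    w[1] * q["Q1", ] + w[2] * q["Q2", ] + (1 - w[1] - w[2]) * q["Q3", ]))
  rownames(freqs) <- paste0("ref", seq_len(n_ref))
  ref <- sample_genotypes(freqs, stats::setNames(rep(1L, n_ref),
                                                 rownames(freqs)),
                          mode = "diploid", seed = seed + 2)
  list(truth = tr, ref = ref, ab = ab)
}

# sparse pseudo-haploid samples from the interior of the same cline
cline_samples <- function(panel, n = 30, missing_rate = 0.7, seed = 9) {
  q <- panel$truth$freq_auto
  set.seed(seed)
  ab <- cbind(runif(n, 0.15, 0.40), runif(n, 0.15, 0.35))
  freqs <- t(apply(ab, 1, function(w)
    w[1] * q["Q1", ] + w[2] * q["Q2", ] + (1 - w[1] - w[2]) * q["Q3", ]))
  rownames(freqs) <- paste0("anc", seq_len(n))
  sample_genotypes(freqs, stats::setNames(rep(1L, n), rownames(freqs)),
                   missing_rate = missing_rate, seed = seed + 1)
}
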