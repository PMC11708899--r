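test_that("drift draws respect the zero-drift limit and the parent mean", {
  specs <- list(pop_spec("zero", f = 1e-8), pop_spec("drifted", f = 0.2))
  tr <- simulate_frequencies(50000, specs, seed = 11)
  expect_lt(max(abs(tr$freq_auto["zero", ] - tr$anc_auto)), 1e-6)
  # law of total expectation: E[child] = E[ancestral]; 3 Monte-Carlo SEs
  diffs <- tr$freq_auto["drifted", ] - tr$anc_auto
  mc_se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * mc_se)
})

test_that("degenerate admixture with weight (1, 0) copies the source", {
  specs <- list(pop_spec("src1", f = 0.1), pop_spec("src2", f = 0.1),
                pop_spec("adm", f = 0, admix = c(src1 = 1, src2 = 0)))
  tr <- simulate_frequencies(500, specs, seed = 3)
  expect_equal(tr$freq_auto["adm", ], tr$freq_auto["src1", ])
})

test_that("sex-biased admixture weights follow the 1/2 and 2/3 rules", {
  w <- sex_biased_weights(c(steppe = 1, farmer = 0), c(steppe = 0, farmer = 1))
  expect_equal(unname(w$auto), c(0.5, 0.5))
  expect_equal(unname(w$x), c(1 / 3, 2 / 3))
  same <- sex_biased_weights(c(a = 0.3, b = 0.7), c(a = 0.3, b = 0.7))
  expect_equal(same$auto, same$x)
  expect_error(sex_biased_weights(c(a = 0.5, b = 0.4), c(a = 0.5, b = 0.5)),
               "sum to 1")
})

test_that("sex-biased chrX track uses the chrX weights", {
  specs <- list(pop_spec("s1", f = 0.05), pop_spec("s2", f = 0.05),
                pop_spec("mix", f = 0,
                         male_w = c(s1 = 1, s2 = 0), female_w = c(s1 = 0, s2 = 1)))
  tr <- simulate_frequencies(2000, specs, seed = 5)
  expect_equal(tr$freq_auto["mix", ],
               0.5 * tr$freq_auto["s1", ] + 0.5 * tr$freq_auto["s2", ])
  expect_equal(tr$freq_x["mix", ],
               (1 / 3) * tr$freq_x["s1", ] + (2 / 3) * tr$freq_x["s2", ])
})

test_that("genotype sampling honours coding, fixation and expectations", {
  freq <- rbind(pop = c(1, rep(0.5, 19999)))
  g <- sample_genotypes(freq, c(pop = 6), missing_rate = 0, seed = 2)
  expect_true(all(g$calls[, 1] == 2L))
  expect_false(any(g$calls == 1L, na.rm = TRUE))      # pseudo-haploid coding
  # binomial expectation: mean(call / 2) matches the mean true frequency
  mean_dose <- mean(g$calls) / 2
  se <- sqrt(mean(0.5 * 0.5) / (6 * 20000))
  expect_lt(abs(mean_dose - mean(freq)), 3 * se + 1e-4)
  d <- sample_genotypes(freq, c(pop = 4), mode = "diploid", seed = 3)
  expect_true(any(d$calls == 1L))
  expect_equal(d$ploidy, rep("diploid", 4))
})

test_that("generators are pure functions of spec and seed", {
  specs <- list(pop_spec("a", f = 0.1), pop_spec("b", f = 0.1))
  t1 <- simulate_frequencies(300, specs, seed = 9)
  t2 <- simulate_frequencies(300, specs, seed = 9)
  expect_identical(t1, t2)
  g1 <- sample_genotypes(t1, c(a = 3, b = 3), missing_rate = 0.2, seed = 4)
  g2 <- sample_genotypes(t2, c(a = 3, b = 3), missing_rate = 0.2, seed = 4)
  expect_identical(g1$calls, g2$calls)
  rc1 <- simulate_read_counts(c("XX", "XY"), 5000, seed = 6)
  rc2 <- simulate_read_counts(c("XX", "XY"), 5000, seed = 6)
  expect_identical(rc1, rc2)
})

test_that("simulated matrices satisfy the genotype invariants", {
  specs <- list(pop_spec("a", f = 0.05))
  tr <- simulate_frequencies(400, specs, seed = 13)
  g <- sample_genotypes(tr, c(a = 5), missing_rate = 0.3, seed = 14)
  expect_s3_class(g, "geno_matrix")   # constructor enforces the invariants
  expect_true(all(diff(g$snps$pos) > 0))
  expect_true(all(g$calls %in% c(0L, 2L, NA)))
})

test_that("Hudson Fst from simulated populations recovers the drift input", {
  f_in <- 0.1
  specs <- list(pop_spec("p1", f = f_in), pop_spec("p2", f = f_in))
  tr <- simulate_frequencies(50000, specs, seed = 21)
  g <- sample_genotypes(tr, c(p1 = 25, p2 = 25), mode = "diploid", seed = 22)
  grp <- attr(g, "group")
  p1 <- colMeans(g$calls[grp == "p1", ]) / 2
  p2 <- colMeans(g$calls[grp == "p2", ]) / 2
  fst <- hudson_fst(p1, p2, 50, 50)
  expect_lt(abs(fst - f_in) / f_in, 0.10)
})

test_that("pedigree simulation respects duplicates and Mendelian sharing", {
  ped <- data.frame(id = c("F1", "F2", "kid", "dup"),
                    pop = "p",
                    father = c(NA, NA, "F1", NA),
                    mother = c(NA, NA, "F2", NA),
                    duplicate_of = c(NA, NA, NA, "F1"))
  tr <- simulate_frequencies(3000, list(pop_spec("p", f = 0.05)), seed = 31)
  gd <- simulate_pedigree(tr, ped, mode = "diploid", seed = 32)
  truth <- attr(gd, "diploid_truth")
  expect_identical(truth["dup", ], truth["F1", ])
  # parent and offspring share at least one allele at every site
  incompatible <- (truth["F1", ] == 0 & gd$calls["kid", ] == 2) |
                  (truth["F1", ] == 2 & gd$calls["kid", ] == 0)
  expect_false(any(incompatible))
  expect_error(simulate_pedigree(tr, data.frame(id = c("a", "b"), pop = "p",
                                                father = c("b", "a"),
                                                mother = c("b", "a")),
                                 seed = 1),
               "cyclic")
})

test_that("pseudo-haploid mismatch rates match the enumeration oracle", {
  for (p in c(0.1, 0.3, 0.5)) {
    freq <- rbind(p = rep(p, 40000))
    ped <- data.frame(id = c("u1", "u2", "par", "off"), pop = "p",
                      father = c(NA, NA, NA, "par"),
                      mother = c(NA, NA, NA, "u1"),
                      duplicate_of = NA)
    g <- simulate_pedigree(freq, ped, seed = round(1000 * p))
    mm_unrel <- mean(g$calls["u2", ] != g$calls["par", ])
    mm_po <- mean(g$calls["par", ] != g$calls["off", ])
    se <- 1 / sqrt(40000)
    expect_lt(abs(mm_unrel - enum_p0(p, "unrelated")), 4 * se)
    expect_lt(abs(mm_po - enum_p0(p, "parent_offspring")), 4 * se)
    expect_lt(mm_po, mm_unrel)
  }
})

test_that("read-count simulation matches its binomial model", {
  rc0 <- simulate_read_counts("XX", 1000, seed = 1, q_female = 0)
  expect_equal(rc0$n_y, 0L)
  rc <- simulate_read_counts(rep("XY", 50), 10000, seed = 2)
  ry <- rc$n_y / (rc$n_x + rc$n_y)
  expect_true(all(abs(ry - 0.25) < 0.02))
})

test_that("chrY call simulation is exact at zero flip error", {
  tree <- data.frame(hg = c("A", "B", "C", "D"), parent = c(NA, "A", "B", "A"))
  ct <- simulate_y_calls(tree, "C", 20, flip_error = 0, seed = 3)
  tal <- tally_y_calls(ct)
  on_lineage <- tal$hg %in% c("A", "B", "C")
  expect_true(all(tal$proportion[on_lineage] == 1))
  expect_true(all(tal$proportion[!on_lineage] == 0))
  ct0 <- simulate_y_calls(tree, "C", c(A = 20, B = 20, C = 20, D = 0),
                          flip_error = 0, seed = 4)
  expect_false("D" %in% ct0$hg)
})

test_that("geographic simulation stays inside its cap", {
  md <- simulate_geo_dates(200, center = c(48, 31), radius_km = 350, seed = 5)
  d <- haversine_km(48, 31, md$lat, md$lon)
  expect_true(all(d <= 350 + 1e-6))
  one <- simulate_geo_dates(1, center = c(10, 10), radius_km = 100, seed = 6)
  expect_equal(minimal_bounding_radius(one$lat, one$lon), 0)
})

test_that("distant clusters are never mixed by geographic matching", {
  spec <- data.frame(lat = c(0, 0), lon = c(0, 179), radius_km = 300,
                     n = 15, date_lo = -500, date_hi = -400)
  md <- simulate_geo_dates(cluster_spec = spec, seed = 7)
  subs <- matched_subsets(md, radius_km = 800, min_size = 5, seed = 8)
  expect_gt(length(subs), 0)
  for (s in subs) {
    gps <- unique(md$group[md$id %in% s$members])
    expect_length(gps, 1)
  }
})
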