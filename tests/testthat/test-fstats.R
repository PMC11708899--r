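test_that("group frequencies count alleles by ploidy", {
  m1 <- toy_matrix(rbind(c(2L)))
  f1 <- group_allele_frequencies(m1, c(ind1 = "g"))
  expect_equal(unname(f1$freq["g", 1]), 1.0)
  expect_equal(unname(f1$count["g", 1]), 1)
  m2 <- toy_matrix(rbind(c(2L), c(0L)), ploidy = "diploid")
  f2 <- group_allele_frequencies(m2, c(ind1 = "g", ind2 = "g"))
  expect_equal(unname(f2$freq["g", 1]), 0.5)
  expect_equal(unname(f2$count["g", 1]), 4)
  m3 <- toy_matrix(rbind(c(NA_integer_, 2L)))
  f3_ <- group_allele_frequencies(m3, c(ind1 = "g"))
  expect_true(is.na(f3_$freq["g", 1]))
  expect_equal(unname(f3_$count["g", 1]), 0)
})

test_that("f4 reproduces the hand-arithmetic oracle and its symmetries", {
  fa <- as_group_freqs(rbind(a = c(.5, .2, .9), b = c(.1, .4, .7),
                             c = c(.6, .6, .5), d = c(.2, .5, .5)))
  r <- f4(fa, "a", "b", "c", "d")
  expect_equal(r$estimate, (0.4 * 0.4 - 0.2 * 0.1 + 0.2 * 0) / 3,
               tolerance = 1e-12)
  expect_equal(r$estimate, 0.0466667, tolerance = 1e-5)
  expect_equal(f4(fa, "b", "a", "c", "d")$estimate, -r$estimate)
  expect_equal(f4(fa, "a", "b", "d", "c")$estimate, -r$estimate)
  # A = B gives an algebraic zero
  fb <- as_group_freqs(rbind(a = c(.5, .2), b = c(.5, .2),
                             c = c(.9, .1), d = c(.3, .3)))
  expect_equal(f4(fb, "a", "b", "c", "d")$estimate, 0)
})

test_that("outgroup f3 reproduces its oracle and is symmetric", {
  fo <- as_group_freqs(rbind(o = c(.9, .1), a = c(.5, .5), b = c(.6, .2)))
  expect_equal(f3(fo, "o", "a", "b")$estimate, 0.08, tolerance = 1e-12)
  expect_equal(f3(fo, "o", "b", "a")$estimate, 0.08, tolerance = 1e-12)
  fs <- as_group_freqs(rbind(o = c(.4, .7), a = c(.4, .7), b = c(.4, .7)))
  expect_equal(f3(fs, "o", "a", "b")$estimate, 0)
})

test_that("block jackknife matches the brute-force oracle", {
  expect_equal(block_jackknife(rep(3.2, 50), rep(1:5, each = 10))$se, 0)
  set.seed(99)
  vals <- rnorm(100)
  blocks <- rep(1:5, each = 20)
  ours <- block_jackknife(vals, blocks)
  oracle <- brute_jackknife(vals, blocks)
  expect_equal(ours$estimate, oracle$estimate, tolerance = 1e-12)
  expect_equal(ours$se, oracle$se, tolerance = 1e-10)
  # uneven blocks: the point estimate is still the plain mean
  uneven <- c(rep(1L, 37), rep(2L, 63))
  expect_equal(block_jackknife(vals, uneven)$estimate, mean(vals))
  expect_error(block_jackknife(vals, rep(1, 100)), "at least 2")
})

test_that("f4 is linear over concatenated SNP sets", {
  set.seed(17)
  mk <- function(n) matrix(runif(4 * n, 0.05, 0.95), nrow = 4,
                           dimnames = list(c("a", "b", "c", "d"), NULL))
  f_1 <- mk(600); f_2 <- mk(400)
  est1 <- f4(as_group_freqs(f_1), "a", "b", "c", "d")$estimate
  est2 <- f4(as_group_freqs(f_2), "a", "b", "c", "d")$estimate
  est12 <- f4(as_group_freqs(cbind(f_1, f_2)), "a", "b", "c", "d")$estimate
  expect_equal(est12, (600 * est1 + 400 * est2) / 1000, tolerance = 1e-12)
})

test_that("jackknife SE scales like 1/sqrt(n_snps)", {
  ses <- vapply(c(5000, 20000, 80000), function(n) {
    specs <- list(pop_spec("o", f = 0.3), pop_spec("a", f = 0.1),
                  pop_spec("b", f = 0.1), pop_spec("t", f = 0.2))
    tr <- simulate_frequencies(n, specs, seed = n + 1)
    f4(as_group_freqs(tr$freq_auto), "o", "t", "a", "b")$se
  }, 0)
  slope <- stats::coef(stats::lm(log(ses) ~ log(c(5000, 20000, 80000))))[2]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("f4 flags the SE when fewer than two blocks are usable", {
  fm <- as_group_freqs(rbind(a = runif(10), b = runif(10),
                             c = runif(10), d = runif(10)))
  r <- f4(fm, "a", "b", "c", "d")  # 10 SNPs, one 500-SNP block
  expect_true(is.na(r$se))
  expect_equal(r$flag, "se_unavailable")
})

test_that("cladality verdicts follow the 95% |Z| rule", {
  # exact equality: every Z is 0, fraction 1, cladal
  set.seed(23)
  base <- matrix(runif(12 * 2000, 0.05, 0.95), nrow = 12,
                 dimnames = list(c("out", "A", "B", paste0("t", 1:9)), NULL))
  base["B", ] <- base["A", ]
  fr <- as_group_freqs(base)
  r <- cladality_test(fr, "A", "B", paste0("t", 1:9), "out")
  expect_true(r$cladal)
  expect_equal(r$fraction_nonsig, 1.0)
  expect_true(all(r$table$estimate == 0))
})

test_that("simulated clades pass and admixed pairs fail the screen", {
  n_rep <- 10
  cladal_ok <- 0
  z_all <- c()
  for (i in seq_len(n_rep)) {
    specs <- c(list(pop_spec("out", f = 0.4),
                    pop_spec("anc_ab", f = 0.1),
                    pop_spec("A", f = 0.02, parent = "anc_ab"),
                    pop_spec("B", f = 0.02, parent = "anc_ab")),
               lapply(1:12, function(k) pop_spec(paste0("t", k), f = 0.05 + 0.01 * k)))
    tr <- simulate_frequencies(20000, specs, seed = 100 + i)
    pops <- rownames(tr$freq_auto)
    g <- sample_genotypes(tr, stats::setNames(rep(5, length(pops)), pops),
                          missing_rate = 0.1, seed = 200 + i)
    fr <- group_allele_frequencies(g)
    r <- cladality_test(fr, "A", "B", paste0("t", 1:12), "out")
    z_all <- c(z_all, r$table$z)
    if (r$cladal) cladal_ok <- cladal_ok + 1
  }
  expect_gte(cladal_ok, 9)
  expect_gte(mean(abs(z_all) <= 3), 0.95)
  # 30% admixture from a panel-related source breaks cladality with the
  # significant Z pointing toward that source
  specs2 <- c(list(pop_spec("out", f = 0.4),
                   pop_spec("anc_ab", f = 0.1),
                   pop_spec("A", f = 0.02, parent = "anc_ab"),
                   pop_spec("B0", f = 0.02, parent = "anc_ab"),
                   pop_spec("intr", f = 0.15),
                   pop_spec("t1", f = 0.02, parent = "intr"),
                   pop_spec("B", f = 0.005, admix = c(B0 = 0.7, intr = 0.3))),
              lapply(2:8, function(k) pop_spec(paste0("t", k), f = 0.08)))
  tr2 <- simulate_frequencies(20000, specs2, seed = 77)
  pops2 <- rownames(tr2$freq_auto)
  g2 <- sample_genotypes(tr2, stats::setNames(rep(5, length(pops2)), pops2),
                         missing_rate = 0.1, seed = 78)
  fr2 <- group_allele_frequencies(g2)
  r2 <- cladality_test(fr2, "A", "B", paste0("t", 1:8), "out")
  expect_false(r2$cladal)
  expect_true("t1" %in% r2$significant$panel_group)
  # shared t1-B drift raises E[t1 * b], so f4(out, t1; A, B) > 0
  expect_gt(r2$table$z[r2$table$panel_group == "t1"], 3)
})

test_that("identical tracks give a zero chrX-autosome contrast", {
  set.seed(31)
  fm <- matrix(runif(6 * 3000, 0.05, 0.95), nrow = 6,
               dimnames = list(c("out", "foc", paste0("t", 1:4)), NULL))
  fr <- as_group_freqs(fm)
  tab <- chrx_autosome_contrast(fr, fr, "out", "foc", paste0("t", 1:4),
                                min_snps_x = 100)
  expect_true(all(tab$d == 0))
})

test_that("male-biased steppe admixture shifts chrX affinity to the female source", {
  hits <- 0
  n_rep <- 10
  for (i in seq_len(n_rep)) {
    specs <- c(list(pop_spec("out", f = 0.4),
                    pop_spec("steppe", f = 0.1),
                    pop_spec("farmer", f = 0.1),
                    pop_spec("steppe_ref", f = 0.02, parent = "steppe"),
                    pop_spec("farmer_ref", f = 0.02, parent = "farmer"),
                    pop_spec("adm", f = 0.005,
                             male_w = c(steppe = 0.9, farmer = 0.1),
                             female_w = c(steppe = 0.1, farmer = 0.9))),
               lapply(1:3, function(k) pop_spec(paste0("t", k), f = 0.15)))
    tr <- simulate_frequencies(15000, specs, seed = 500 + i, n_snps_x = 15000)
    fr_a <- as_group_freqs(tr$freq_auto)
    fr_x <- as_group_freqs(tr$freq_x)
    panel <- c("steppe_ref", "farmer_ref", paste0("t", 1:3))
    tab <- chrx_autosome_contrast(fr_a, fr_x, "out", "adm", panel,
                                  min_snps_x = 1000)
    d_farm <- tab$d[tab$panel_group == "farmer_ref"]
    d_step <- tab$d[tab$panel_group == "steppe_ref"]
    if (d_farm > 0 && d_step < 0) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("the chrX SNP floor drops sparse panel entries", {
  set.seed(41)
  fa <- matrix(runif(4 * 3000, 0.05, 0.95), nrow = 4,
               dimnames = list(c("out", "foc", "t1", "t2"), NULL))
  fx <- fa
  fx["t2", 2:3000] <- NA  # one usable chrX SNP for t2
  tab <- chrx_autosome_contrast(as_group_freqs(fa), as_group_freqs(fx),
                                "out", "foc", c("t1", "t2"), min_snps_x = 1000)
  expect_equal(tab$panel_group, "t1")
  fx["t1", 2:3000] <- NA
  expect_error(chrx_autosome_contrast(as_group_freqs(fa), as_group_freqs(fx),
                                      "out", "foc", c("t1", "t2"),
                                      min_snps_x = 1000),
               "below the chrX SNP threshold")
})
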