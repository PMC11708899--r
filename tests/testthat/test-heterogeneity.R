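test_that("the cohort fixture bins to the published counts", {
  md <- load_north_pontic_metadata()
  res <- assign_date_bins(md, exclusions = north_pontic_exclusions)
  expect_equal(unname(res$counts), c(15L, 27L, 26L, 19L))
  expect_length(res$unassigned, 0)
  expect_setequal(res$excluded, north_pontic_exclusions)
  # a Hellenistic-period burial with midpoint -299 falls in the third bin
  expect_true("UKR152" %in% res$members$IAEMA)
  expect_equal((md$date_lo + md$date_hi)[md$id == "UKR152"] / 2, -299)
})

test_that("bin boundaries are upper-inclusive", {
  md <- data.frame(id = c("edge", "first_lo"),
                   date_lo = c(-300, -3000), date_hi = c(-300, -3000))
  res <- assign_date_bins(md)
  expect_true("edge" %in% res$members$SEIA)       # upper bound belongs to SEIA
  expect_true("first_lo" %in% res$members$LBAEIA) # first bin closed below
})

test_that("haversine distances match closed forms and an independent oracle", {
  expect_equal(haversine_km(12, 34, 12, 34), 0)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-6)
  expect_equal(haversine_km(0, 0, 0, 90), pi * 6371 / 2, tolerance = 1e-6)
  set.seed(171)
  lat <- runif(20, -80, 80); lon <- runif(20, -180, 180)
  lat2 <- runif(20, -80, 80); lon2 <- runif(20, -180, 180)
  ours <- haversine_km(lat, lon, lat2, lon2)
  oracle <- geosphere::distHaversine(cbind(lon, lat), cbind(lon2, lat2),
                                     r = 6371000) / 1000
  expect_equal(ours, oracle, tolerance = 1e-9)
})

test_that("minimal bounding radius equals the exhaustive cap oracle", {
  expect_equal(minimal_bounding_radius(48.2, 31.1), 0)
  # two points: half their separation
  d2 <- haversine_km(48, 30, 51, 36)
  expect_equal(minimal_bounding_radius(c(48, 51), c(30, 36)), d2 / 2,
               tolerance = 1e-6)
  set.seed(181)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    lat <- runif(n, 40, 55); lon <- runif(n, 20, 45)
    expect_equal(minimal_bounding_radius(lat, lon),
                 brute_min_cap_km(lat, lon), tolerance = 1e-6)
  }
})

test_that("matched subsets respect eligibility, radius and counts", {
  tight <- simulate_geo_dates(30, center = c(49, 32), radius_km = 50, seed = 191)
  subs <- matched_subsets(tight, radius_km = 200, min_size = 10, seed = 1)
  expect_length(subs, 30)
  sizes <- vapply(subs, `[[`, 0L, "size")
  expect_true(all(sizes == 30))      # one tight cluster: identical membership
  for (s in subs[1:3]) {
    seed_row <- tight[tight$id == s$seed, ]
    member_rows <- tight[match(s$members, tight$id), ]
    expect_true(all(haversine_km(seed_row$lat, seed_row$lon,
                                 member_rows$lat, member_rows$lon) <= 200 + 1e-6))
  }
  # eligibility bounded: 28 eligible seeds yield exactly 28 subsets
  few <- simulate_geo_dates(28, center = c(49, 32), radius_km = 50, seed = 192)
  subs28 <- matched_subsets(few, radius_km = 200, max_subsets = 100,
                            min_size = 10, seed = 2)
  expect_length(subs28, 28)
  # reproducibility per seed
  subs_again <- matched_subsets(tight, radius_km = 200, min_size = 10, seed = 1)
  expect_identical(lapply(subs, `[[`, "seed"), lapply(subs_again, `[[`, "seed"))
  # no eligible seed: empty result with a warning
  sparse <- simulate_geo_dates(5, center = c(49, 32), radius_km = 2000, seed = 193)
  expect_warning(empty <- matched_subsets(sparse, radius_km = 10,
                                          min_size = 10, seed = 3),
                 "neighbourhood")
  expect_length(empty, 0)
  # the strict variant needs strictly more than min_size other members
  expect_warning(
    strict29 <- matched_subsets(tight, radius_km = 200, min_size = 29,
                                seed = 4, strict_gt_others = TRUE),
    "neighbourhood")
  expect_length(strict29, 0)   # 29 others is not > 29
  strict28 <- matched_subsets(tight, radius_km = 200, min_size = 28,
                              seed = 4, strict_gt_others = TRUE)
  expect_length(strict28, 30)  # 29 others > 28
})

test_that("distance sets have the right size and geometry", {
  coords <- matrix(rnorm(15 * 25), nrow = 15,
                   dimnames = list(paste0("s", 1:15), NULL))
  ds <- pairwise_distance_set(coords, paste0("s", 1:15))
  expect_length(ds$distances, 105)
  same <- matrix(1, nrow = 4, ncol = 3,
                 dimnames = list(paste0("a", 1:4), NULL))
  expect_true(all(pairwise_distance_set(same, paste0("a", 1:4))$distances == 0))
  tri <- rbind(p1 = c(0, 0), p2 = c(3, 0), p3 = c(0, 4))
  expect_setequal(pairwise_distance_set(tri, rownames(tri))$distances,
                  c(3, 4, 5))
  expect_error(pairwise_distance_set(tri, "p1"), "at least 2")
})

test_that("the heterogeneity report behaves on degenerate and scaled input", {
  set.seed(201)
  coords <- matrix(rnorm(12 * 25), nrow = 12,
                   dimnames = list(paste0("s", 1:12), NULL))
  study <- pairwise_distance_set(coords, paste0("s", 1:12), "study")
  rep1 <- heterogeneity_report(study, list(study))
  expect_equal(rep1$exceedance_fraction, 1.0)
  # every KDE integrates to ~1 on its grid
  area <- sum(rep1$study_kde$y) * diff(rep1$study_kde$x[1:2])
  expect_equal(area, 1, tolerance = 0.01)
  expect_error(heterogeneity_report(study, list()), "at least one")
  # exceedance is invariant to a common rescaling of all coordinates
  coords2 <- coords * 7.3
  study2 <- pairwise_distance_set(coords2, paste0("s", 1:12), "study")
  set.seed(202)
  subs_ids <- lapply(1:5, function(i) sample(rownames(coords), 6))
  subs_a <- lapply(seq_along(subs_ids), function(i)
    pairwise_distance_set(coords, subs_ids[[i]], paste0("sub", i)))
  subs_b <- lapply(seq_along(subs_ids), function(i)
    pairwise_distance_set(coords2, subs_ids[[i]], paste0("sub", i)))
  expect_equal(heterogeneity_report(study, subs_a)$exceedance_fraction,
               heterogeneity_report(study2, subs_b)$exceedance_fraction)
})

test_that("a two-population study set exceeds single-population matched subsets", {
  # scaled-down replicate of the headline contrast; the acceptance suite
  # runs the full replicated version
  specs <- list(pop_spec("P1", f = 0.1), pop_spec("P2", f = 0.1))
  tr <- simulate_frequencies(4000, specs, seed = 211)
  ref <- sample_genotypes(tr, c(P1 = 30, P2 = 30), mode = "diploid", seed = 212)
  model <- fit_pca(ref, 10)
  study_g <- sample_genotypes(tr, c(P1 = 8, P2 = 7), missing_rate = 0.5,
                              seed = 213)
  study_g$samples <- paste0("st_", study_g$samples)
  rownames(study_g$calls) <- study_g$samples
  panel_g <- sample_genotypes(tr, c(P1 = 40), missing_rate = 0.3, seed = 214)
  panel_g$samples <- paste0("ref_", panel_g$samples)
  rownames(panel_g$calls) <- panel_g$samples
  sc_study <- scaled_coordinate_matrix(model, project_lsq(model, study_g), 10)
  sc_panel <- scaled_coordinate_matrix(model, project_lsq(model, panel_g), 10)
  geo <- simulate_geo_dates(40, center = c(49, 32), radius_km = 300, seed = 215)
  geo$id <- rownames(sc_panel)
  subs <- matched_subsets(geo, 250, min_size = 10, seed = 216)
  dsets <- lapply(subs, function(s)
    pairwise_distance_set(sc_panel, s$members, s$seed))
  rep_ <- heterogeneity_report(
    pairwise_distance_set(sc_study, rownames(sc_study), "study"), dsets)
  expect_equal(rep_$exceedance_fraction, 0)
})
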