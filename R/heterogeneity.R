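#' Geographically matched test for ancestry heterogeneity
#'
#' The heterogeneity of a study cohort is summarised by the pairwise
#' Euclidean distances between its members in eigenvalue-scaled PC space
#' (first 25 components by default), within date bins defined on date-range
#' midpoints. A null is built from a large reference panel: up to 100
#' panel members are drawn as subset seeds, each seed retaining every panel
#' genome within the study cohort's minimal-bounding-circle radius, so each
#' subset is as geographically concentrated as the study sample. The
#' study mean distance is compared to the subset means via an exceedance
#' fraction, and kernel density estimates of the distance sets are
#' returned for plotting.
#'
#' @name heterogeneity
NULL

#' Date bins used for the North Pontic cohort
#'
#' Four contiguous analysis windows on the signed-year axis: Late Bronze
#' Age to pre-Scythian Early Iron Age (3000-700 BCE), Scythian-period Early
#' Iron Age (699-300 BCE), post-Scythian Iron Age to Early Middle Ages
#' (299 BCE-900 CE), and Middle Ages to early modern (901-1800 CE).
#'
#' @return Data frame (`name`, `lower`, `upper`); `lower` is exclusive
#'   except for the first bin.
#' @export
default_date_bins <- function() {
  data.frame(name = c("LBAEIA", "SEIA", "IAEMA", "MAEM"),
             lower = c(-3000, -700, -300, 900),
             upper = c(-700, -300, 900, 1800),
             stringsAsFactors = FALSE)
}

#' Assign individuals to date bins by range midpoint
#'
#' The midpoint `(date_lo + date_hi) / 2` places each individual; a bin
#' covers `(lower, upper]` on the signed axis, except the first bin which
#' includes its lower bound. Individuals in `exclusions` are never
#' assigned; midpoints falling in no bin are reported as unassigned.
#'
#' @param metadata data frame with `id`, `date_lo`, `date_hi` (e.g. from
#'   [read_sample_metadata()]).
#' @param bins data frame (`name`, `lower`, `upper`), ordered, contiguous.
#' @param exclusions character vector of ids to leave out.
#' @return A list: `members` (named list of id vectors per bin), `counts`,
#'   `unassigned`, `excluded`.
#' @export
assign_date_bins <- function(metadata, bins = default_date_bins(),
                             exclusions = character(0)) {
  stopifnot(all(c("id", "date_lo", "date_hi") %in% names(metadata)))
  if (any(diff(bins$lower) <= 0) || any(bins$upper <= bins$lower))
    stop("bins must be ordered and non-degenerate")
  md <- metadata[!(metadata$id %in% exclusions), , drop = FALSE]
  mid <- (md$date_lo + md$date_hi) / 2
  bin_of <- rep(NA_character_, nrow(md))
  for (i in seq_len(nrow(bins))) {
    inb <- if (i == 1) mid >= bins$lower[i] & mid <= bins$upper[i]
           else mid > bins$lower[i] & mid <= bins$upper[i]
    bin_of[inb & is.na(bin_of)] <- bins$name[i]
  }
  members <- lapply(bins$name, function(b) md$id[!is.na(bin_of) & bin_of == b])
  names(members) <- bins$name
  list(members = members,
       counts = vapply(members, length, 0L),
       unassigned = md$id[is.na(bin_of)],
       excluded = intersect(metadata$id, exclusions))
}

#' Great-circle distance by the haversine formula
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @param radius_km Earth radius (default 6371.0 km).
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371.0) {
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dl <- .deg2rad(lon2 - lon1); dp <- p2 - p1
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

.to_unit_xyz <- function(lat, lon) {
  la <- .deg2rad(lat); lo <- .deg2rad(lon)
  cbind(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
}

.cap_from_support <- function(P) {
  # smallest spherical cap with the support points on its boundary
  if (nrow(P) == 0) return(list(axis = c(0, 0, 1), cosr = Inf))
  if (nrow(P) == 1) return(list(axis = P[1, ], cosr = 1))
  if (nrow(P) == 2) {
    ax <- P[1, ] + P[2, ]
    nrm <- sqrt(sum(ax^2))
    if (nrm < 1e-12) return(list(axis = c(0, 0, 1), cosr = -1)) # antipodal
    ax <- ax / nrm
    return(list(axis = ax, cosr = sum(ax * P[1, ])))
  }
  ax <- .cross3(P[2, ] - P[1, ], P[3, ] - P[1, ])
  nrm <- sqrt(sum(ax^2))
  if (nrm < 1e-12) {
    # collinear on a great circle: fall back to the widest pair
    pairs <- utils::combn(3, 2)
    best <- NULL
    for (j in seq_len(ncol(pairs))) {
      cand <- .cap_from_support(P[pairs[, j], , drop = FALSE])
      if (is.null(best) || cand$cosr < best$cosr) best <- cand
    }
    return(best)
  }
  ax <- ax / nrm
  if (sum(ax * P[1, ]) < 0) ax <- -ax  # smaller of the two caps
  list(axis = ax, cosr = sum(ax * P[1, ]))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.cap_contains <- function(cap, p, tol = 1e-10) {
  sum(cap$axis * p) >= cap$cosr - tol
}

.welzl_cap <- function(P, R) {
  if (nrow(P) == 0 || nrow(R) == 3) return(.cap_from_support(R))
  p <- P[1, , drop = FALSE]
  cap <- .welzl_cap(P[-1, , drop = FALSE], R)
  if (.cap_contains(cap, p[1, ])) return(cap)
  .welzl_cap(P[-1, , drop = FALSE], rbind(R, p))
}

#' Radius of the minimal bounding circle of geographic points
#'
#' Smallest spherical cap containing all points, computed by Welzl's
#' move-to-front algorithm on the 3-D unit-sphere embedding (support sets
#' of at most three points determine a cap). Intended for point sets
#' well within a hemisphere, as geographic site clusters are.
#'
#' @param lat,lon coordinates in decimal degrees.
#' @param seed permutation seed for the randomised algorithm (the result
#'   is deterministic; the permutation only affects runtime).
#' @return Great-circle radius in km.
#' @export
minimal_bounding_radius <- function(lat, lon, seed = 1) {
  stopifnot(length(lat) >= 1, length(lat) == length(lon))
  P <- .to_unit_xyz(lat, lon)
  if (nrow(P) == 1) return(0)
  set.seed(seed)
  P <- P[sample(nrow(P)), , drop = FALSE]
  cap <- .welzl_cap(P, P[0, , drop = FALSE])
  acos(pmin(1, pmax(-1, cap$cosr))) * 6371.0
}

#' Geographically matched random subsets of a reference panel
#'
#' A panel member is an eligible seed when its neighbourhood (itself plus
#' all panel members within `radius_km` by great-circle distance) has at
#' least `min_size` members (set `strict_gt_others = TRUE` to require
#' strictly more than `min_size` *other* members). Up to `max_subsets`
#' distinct seeds are drawn uniformly without replacement; each seed yields
#' one subset consisting of its whole neighbourhood.
#'
#' @param panel_metadata data frame with `id`, `lat`, `lon`.
#' @param radius_km matching radius (e.g. the study set's minimal bounding
#'   radius).
#' @param max_subsets maximum number of subsets (default 100).
#' @param min_size minimum subset size counting the seed (default 10).
#' @param seed RNG seed for the seed draw.
#' @param strict_gt_others eligibility variant counting neighbours only.
#' @return List of subsets (`seed`, `members`, `size`); empty with a
#'   warning when no seed is eligible.
#' @export
matched_subsets <- function(panel_metadata, radius_km, max_subsets = 100,
                            min_size = 10, seed = 1, strict_gt_others = FALSE) {
  md <- panel_metadata
  stopifnot(all(c("id", "lat", "lon") %in% names(md)))
  n <- nrow(md)
  xyz <- .to_unit_xyz(md$lat, md$lon)
  cos_thresh <- cos(radius_km / 6371.0)
  G <- tcrossprod(xyz) >= cos_thresh - 1e-12
  sizes <- rowSums(G)
  eligible <- if (strict_gt_others) (sizes - 1) > min_size else sizes >= min_size
  if (!any(eligible)) {
    warning("no panel member has a large enough neighbourhood")
    return(list())
  }
  set.seed(seed)
  seeds <- sample(which(eligible), min(max_subsets, sum(eligible)))
  lapply(seeds, function(i) {
    members <- md$id[G[i, ]]
    list(seed = md$id[i], members = members, size = length(members))
  })
}

#' Pairwise Euclidean distance set in scaled PC space
#'
#' @param scaled_coords matrix of eigenvalue-scaled coordinates, samples in
#'   rows (named).
#' @param member_ids ids of the set members.
#' @param label set label.
#' @return A `distance_set`: `label`, `distances` (length `n(n-1)/2`),
#'   `mean`, `n`.
#' @export
pairwise_distance_set <- function(scaled_coords, member_ids, label = "set") {
  missing <- setdiff(member_ids, rownames(scaled_coords))
  if (length(missing))
    stop("no coordinates for: ", paste(missing, collapse = ", "))
  if (length(member_ids) < 2) stop("a distance set needs at least 2 members")
  d <- as.numeric(stats::dist(scaled_coords[member_ids, , drop = FALSE]))
  structure(list(label = label, distances = d, mean = mean(d),
                 n = length(member_ids)),
            class = "distance_set")
}

#' Heterogeneity report: exceedance fraction and KDEs
#'
#' Compares the study cohort's mean pairwise distance with the means of the
#' matched reference subsets. The exceedance fraction is the share of
#' subsets whose mean is at least the study mean; a fraction of 0 means no
#' equally-concentrated reference subset is as heterogeneous as the study
#' set. Gaussian kernel densities for all sets are evaluated on a shared
#' grid for plotting.
#'
#' @param study_set a `distance_set` for the study cohort.
#' @param subset_sets list of `distance_set`s for the matched subsets.
#' @param kde_bandwidth bandwidth; default Silverman's rule per set.
#' @param grid_n grid resolution.
#' @param density_cutoff optional cap on reported densities (display aid).
#' @return A `heterogeneity_report` list.
#' @export
heterogeneity_report <- function(study_set, subset_sets, kde_bandwidth = NULL,
                                 grid_n = 512, density_cutoff = NULL) {
  if (!length(subset_sets)) stop("need at least one matched subset")
  subset_means <- vapply(subset_sets, `[[`, 0, "mean")
  exceedance <- mean(subset_means >= study_set$mean)
  all_sets <- c(list(study_set), subset_sets)
  bws <- vapply(all_sets, function(ds) {
    if (is.null(kde_bandwidth)) stats::bw.nrd0(ds$distances) else kde_bandwidth
  }, 0)
  all_d <- unlist(lapply(all_sets, `[[`, "distances"))
  pad <- 3 * max(bws)   # keep the Gaussian tails on the grid
  grid <- seq(min(all_d) - pad, max(all_d) + pad, length.out = grid_n)
  kde_on_grid <- function(ds) {
    bw <- if (is.null(kde_bandwidth)) stats::bw.nrd0(ds$distances) else kde_bandwidth
    dens <- stats::density(ds$distances, bw = bw, from = grid[1],
                           to = grid[grid_n], n = grid_n)
    y <- dens$y
    if (!is.null(density_cutoff)) y <- pmin(y, density_cutoff)
    list(label = ds$label, x = dens$x, y = y, bw = bw)
  }
  structure(list(study_mean = study_set$mean,
                 subset_means = subset_means,
                 exceedance_fraction = exceedance,
                 n_subsets = length(subset_sets),
                 study_kde = kde_on_grid(study_set),
                 subset_kdes = lapply(subset_sets, kde_on_grid),
                 density_cutoff = density_cutoff),
            class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("heterogeneity: study mean %.4g vs %d matched subsets (mean of means %.4g)\n",
              x$study_mean, x$n_subsets, mean(x$subset_means)))
  cat(sprintf("  exceedance fraction (subset mean >= study mean): %.3f\n",
              x$exceedance_fraction))
  invisible(x)
}
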