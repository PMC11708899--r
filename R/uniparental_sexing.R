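#' Genetic sexing and Y-chromosome haplogroup scoring
#'
#' Genetic sex is called from the fraction of sex-chromosome reads mapping
#' to chrY (the Ry statistic): XY individuals have Ry near the Y/X mapping
#' ratio, XX individuals near zero up to residual mismapping. A 95%
#' Wilson score interval on Ry is compared to two thresholds; calls are
#' ambiguous when the interval is not clearly on one side. chrY
#' haplogroups are scored from tables of haplogroup-informative positions:
#' the assignment is the haplogroup with the highest proportion of
#' positions called in the derived state, subject to a minimum-evidence
#' rule.
#'
#' @name uniparental_sexing
NULL

.wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(lo = pmax(0, center - half), hi = pmin(1, center + half))
}

#' Assign genetic sex from X/Y read counts
#'
#' `XY` when the Ry confidence interval lies entirely above `t_male`;
#' `XX` when it lies entirely below `t_female`; otherwise `ambiguous`.
#'
#' @param n_x,n_y reads mapping to chrX and chrY (vectorised).
#' @param t_female,t_male decision thresholds on Ry (defaults 0.016 and
#'   0.075, the convention of read-fraction sexing of shotgun data).
#' @param conf confidence level of the Wilson interval.
#' @return Data frame (`n_x`, `n_y`, `ry`, `ci_lo`, `ci_hi`, `sex`).
#' @export
assign_sex <- function(n_x, n_y, t_female = 0.016, t_male = 0.075,
                       conf = 0.95) {
  total <- n_x + n_y
  if (any(total <= 0)) stop("zero sex-chromosome reads")
  ci <- .wilson_ci(n_y, total, conf)
  sex <- rep("ambiguous", length(total))
  sex[ci[, "lo"] > t_male] <- "XY"
  sex[ci[, "hi"] < t_female] <- "XX"
  data.frame(n_x = n_x, n_y = n_y, ry = n_y / total,
             ci_lo = ci[, "lo"], ci_hi = ci[, "hi"], sex = sex)
}

#' Tally a chrY call table per haplogroup
#'
#' @param call_table data frame (`hg`, `state`) as from
#'   [simulate_y_calls()] or a real caller.
#' @return Data frame (`hg`, `n_called`, `n_derived`, `proportion`).
#' @export
tally_y_calls <- function(call_table) {
  if (!nrow(call_table))
    return(data.frame(hg = character(0), n_called = integer(0),
                      n_derived = integer(0), proportion = numeric(0)))
  n_called <- table(call_table$hg)
  n_derived <- table(factor(call_table$hg[call_table$state == "derived"],
                            levels = names(n_called)))
  data.frame(hg = names(n_called),
             n_called = as.integer(n_called),
             n_derived = as.integer(n_derived),
             proportion = as.integer(n_derived) / as.integer(n_called),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Score chrY haplogroups from an informative-position call table
#'
#' A haplogroup is a candidate when it has at least `min_calls` called
#' positions and a strict majority of them derived (the minimum-evidence
#' rule that leaves XX individuals, whose sparse spurious chrY calls carry
#' the ancestral allele, unassigned). Without a tree the candidate with
#' the highest derived proportion is assigned, ties broken by the larger
#' number of calls, unresolved ties flagged. With a tree, lineage
#' accumulation applies: a true carrier is derived along the whole path
#' from the root, so among candidates whose called ancestors are also
#' majority derived, the deepest node is assigned (its ancestors tie with
#' it in derived proportion up to noise, so depth -- not the noisy argmax
#' -- identifies the terminal haplogroup).
#'
#' @param call_table data frame (`hg`, `state`).
#' @param min_calls minimum called positions per haplogroup (default 3).
#' @param tree optional haplogroup tree (see [y_tree()]).
#' @return List `haplogroup` (NA when unassigned), `proportion`,
#'   `n_called`, `tie` flag and the per-haplogroup `tallies`.
#' @export
score_y_haplogroups <- function(call_table, min_calls = 3, tree = NULL) {
  tal <- tally_y_calls(call_table)
  cand <- tal[tal$n_called >= min_calls & tal$proportion > 0.5, , drop = FALSE]
  unassigned <- list(haplogroup = NA_character_, proportion = NA_real_,
                     n_called = 0L, tie = FALSE, tallies = tal)
  if (!nrow(cand)) return(unassigned)
  tie <- FALSE
  if (!is.null(tree)) {
    tree <- y_tree(tree)
    majority <- stats::setNames(tal$proportion > 0.5, tal$hg)
    consistent <- vapply(cand$hg, function(hg) {
      lineage <- .y_lineage(tree, hg)
      called <- lineage[lineage %in% tal$hg]
      all(majority[called])
    }, TRUE)
    cand <- cand[consistent, , drop = FALSE]
    if (!nrow(cand)) return(unassigned)
    depth <- tree$depth[match(cand$hg, tree$hg)]
    cand <- cand[depth == max(depth), , drop = FALSE]
  }
  cand <- cand[cand$proportion == max(cand$proportion), , drop = FALSE]
  if (nrow(cand) > 1) cand <- cand[cand$n_called == max(cand$n_called), ,
                                   drop = FALSE]
  if (nrow(cand) > 1) { tie <- TRUE; cand <- cand[1, , drop = FALSE] }
  list(haplogroup = cand$hg, proportion = cand$proportion,
       n_called = cand$n_called, tie = tie, tallies = tal)
}

#' Tally genetic sexes in a metadata table
#'
#' @param metadata data frame with a `sex` column (`XX` / `XY` / other).
#' @return Named integer vector `c(n_xx, n_xy, n_unknown)`.
#' @export
sex_tally <- function(metadata) {
  s <- metadata$sex
  c(n_xx = sum(s == "XX", na.rm = TRUE),
    n_xy = sum(s == "XY", na.rm = TRUE),
    n_unknown = sum(is.na(s) | !(s %in% c("XX", "XY"))))
}
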