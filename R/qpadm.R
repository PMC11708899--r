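#' qpAdm-style admixture-proportion estimation
#'
#' A target population T is modelled as a mixture of k source ("left")
#' populations S_1..S_k with weights w summing to 1. Against a set of
#' reference ("right") populations r_0..r_m that are differentially related
#' to the sources, the admixture identity is exactly linear in w for
#' statistics of the form
#'   y_j = f4(T, r_0; r_0, r_j),   B_ij = f4(S_i, r_0; r_0, r_j),
#' giving y = B' w under the model. Weights are fitted by constrained
#' generalised least squares with the block-jackknife covariance of the
#' residual vector (two-pass: OLS weights, then covariance, then GLS); the
#' minimised quadratic form is compared to a chi-square distribution with
#' `n_right - n_left + 1` degrees of freedom to give the model p-value.
#' Standard errors come from delete-one-block refitting.
#'
#' @name qpadm
NULL

#' Build the f4 system relating a target and sources to right populations
#'
#' Uses the SNPs observed in every modelled group (complete-case
#' intersection). Per-block sums are retained for the jackknife.
#'
#' @param freqs `group_freqs`.
#' @param target target group label.
#' @param sources character vector of source ("left") labels.
#' @param right character vector of right labels; the first entry is the
#'   reference basis r_0. At least `length(sources) + 2` entries required.
#' @param block_size jackknife block size in SNPs.
#' @return A `qpadm_system` list: `y` (length m), `B` (k x m), per-block
#'   arrays, SNP/block counts and labels.
#' @export
build_f4_system <- function(freqs, target, sources, right, block_size = 500) {
  if (length(right) < length(sources) + 2)
    stop("need at least ", length(sources) + 2, " right populations")
  if (target %in% right || any(sources %in% right))
    stop("left and right population sets must be disjoint")
  all_groups <- c(target, sources, right)
  fm <- .freq_rows(freqs, all_groups)
  used <- which(colSums(is.na(fm)) == 0)
  if (!length(used)) stop("no SNP observed in all modelled groups")
  fm <- fm[, used, drop = FALSE]
  blocks <- make_blocks(ncol(freqs$freq), block_size)[used]
  k <- length(sources); m <- length(right) - 1L
  r0 <- fm[1 + k + 1, ]
  left <- fm[seq_len(k + 1), , drop = FALSE]       # target then sources
  # per-SNP products, rows = (target, sources), slices = right[-1]
  ublocks <- sort(unique(blocks))
  g <- length(ublocks)
  bidx <- match(blocks, ublocks)
  sums <- array(0, dim = c(k + 1, m, g))
  for (j in seq_len(m)) {
    rj <- fm[1 + k + 1 + j, ]
    # (left - r0) * (r0 - rj), row-wise over (target, sources)
    prod_j <- sweep(left, 2, r0) * rep(r0 - rj, each = k + 1)
    sums[, j, ] <- t(rowsum(t(prod_j), bidx))
  }
  m_sizes <- as.vector(table(bidx))
  n <- length(used)
  total <- apply(sums, c(1, 2), sum)
  means <- total / n
  structure(list(y = means[1, ], B = means[-1, , drop = FALSE],
                 block_sums = sums, block_sizes = m_sizes,
                 n_snps = n, n_blocks = g,
                 target = target, sources = sources, right = right,
                 block_size = block_size),
            class = "qpadm_system")
}

.solve_gls <- function(B, y, Sigma_inv) {
  k <- nrow(B)
  if (k == 1) return(1)
  A <- B %*% Sigma_inv %*% t(B)
  b <- drop(B %*% Sigma_inv %*% y)
  # sources a right set cannot tell apart leave A near-singular; the
  # spectral pseudo-inverse keeps the fit bounded in that subspace
  Ai <- .safe_inverse(A)$inv
  one <- rep(1, k)
  lam <- (1 - sum(Ai %*% b)) / sum(Ai %*% one)
  drop(Ai %*% (b + lam * one))
}

.safe_inverse <- function(S, tol = 1e-10) {
  # spectral pseudo-inverse: directions with (near-)zero variance carry no
  # information (e.g. a duplicated right population) and are projected out
  eg <- eigen(S, symmetric = TRUE)
  pos <- eg$values > tol * max(eg$values)
  if (!any(pos)) stop("residual covariance is numerically zero")
  V <- eg$vectors[, pos, drop = FALSE]
  list(inv = V %*% (t(V) / eg$values[pos]), n_dropped = sum(!pos))
}

#' Fit admixture weights on a qpAdm system
#'
#' @param system a `qpadm_system` from [build_f4_system()].
#' @return A `qpadm_result`: `weights`, `se`, `p_value`, `df`, `chisq`,
#'   `n_snps`, `n_blocks`, `plausible` (all point estimates in `[0, 1]`),
#'   and `n_dropped_dims`, the number of zero-variance residual directions
#'   projected out of a singular covariance.
#' @export
fit_weights <- function(system) {
  stopifnot(inherits(system, "qpadm_system"))
  k <- length(system$sources)
  m <- length(system$y)
  df <- length(system$right) - (k + 1) + 1
  if (df <= 0) stop("non-positive degrees of freedom")
  g <- system$n_blocks
  if (g < 2) stop("need at least 2 jackknife blocks")
  n <- system$n_snps
  sums <- system$block_sums
  msz <- system$block_sizes
  total <- apply(sums, c(1, 2), sum)
  # delete-one-block means of (y; B), dimension (k+1) x m x g
  loo <- array(NA_real_, dim = dim(sums))
  for (j in seq_len(g)) loo[, , j] <- (total - sums[, , j]) / (n - msz[j])
  # pass 1: GLS under the jackknife covariance of y. Unlike an OLS start,
  # this metric is invariant to duplicated right populations (a duplicated
  # equation carries a perfectly correlated error and no new information),
  # which keeps the whole two-pass fit duplicate-invariant.
  y_loo <- matrix(loo[1, , ], nrow = m)
  Sy <- tcrossprod(y_loo - rowMeans(y_loo)) * (g - 1) / g
  w0 <- if (max(diag(Sy)) > 0) {
    .solve_gls(system$B, system$y, .safe_inverse(Sy)$inv)
  } else {
    .solve_ols(system$B, system$y)
  }
  # residual vectors per delete-one-block replicate at w0
  resid_loo <- vapply(seq_len(g), function(j) {
    yj <- loo[1, , j]; Bj <- loo[-1, , j, drop = FALSE]
    dim(Bj) <- c(k, m)
    yj - drop(crossprod(Bj, w0))
  }, numeric(m))
  resid_loo <- matrix(resid_loo, nrow = m)
  rbar <- rowMeans(resid_loo)
  Sigma <- tcrossprod(resid_loo - rbar) * (g - 1) / g
  scale0 <- max(diag(Sy), .Machine$double.xmin)
  if (max(diag(Sigma)) <= 1e-20 * scale0) {
    # the model fits exactly (e.g. the target duplicates a source)
    return(structure(list(target = system$target, sources = system$sources,
                          weights = stats::setNames(w0, system$sources),
                          se = stats::setNames(rep(0, k), system$sources),
                          chisq = 0, p_value = 1, df = df,
                          n_snps = n, n_blocks = g,
                          plausible = all(w0 >= 0 & w0 <= 1),
                          n_dropped_dims = 0L),
                     class = "qpadm_result"))
  }
  si <- .safe_inverse(Sigma)
  # pass 2: GLS weights
  w <- .solve_gls(system$B, system$y, si$inv)
  resid <- system$y - drop(crossprod(matrix(system$B, nrow = k), w))
  chisq <- drop(t(resid) %*% si$inv %*% resid)
  # the covariance is estimated from g jackknife blocks, so the quadratic
  # form follows Hotelling's T^2 rather than chi-square; use the F
  # transform when enough blocks are available
  p <- if (g - df > 1) {
    stats::pf(chisq * (g - df) / (df * (g - 1)), df, g - df,
              lower.tail = FALSE)
  } else {
    stats::pchisq(chisq, df, lower.tail = FALSE)
  }
  # delete-one-block refits (fixed covariance) for weight SEs
  w_loo <- vapply(seq_len(g), function(j) {
    Bj <- loo[-1, , j, drop = FALSE]
    dim(Bj) <- c(k, m)
    .solve_gls(Bj, loo[1, , j], si$inv)
  }, numeric(k))
  w_loo <- matrix(w_loo, nrow = k)
  se <- sqrt(rowSums((w_loo - rowMeans(w_loo))^2) * (g - 1) / g)
  structure(list(target = system$target, sources = system$sources,
                 weights = stats::setNames(w, system$sources),
                 se = stats::setNames(se, system$sources),
                 chisq = chisq, p_value = p, df = df,
                 n_snps = n, n_blocks = g,
                 plausible = all(w >= 0 & w <= 1),
                 n_dropped_dims = si$n_dropped),
            class = "qpadm_result")
}

.solve_ols <- function(B, y) {
  k <- nrow(B)
  if (k == 1) return(1)
  # parameterise w = w_base + C z with sum(w) = 1
  w_base <- c(1, rep(0, k - 1))
  C <- rbind(-1, diag(k - 1))
  X <- t(B) %*% C
  r0 <- y - drop(t(B) %*% w_base)
  z <- tryCatch(qr.solve(X, r0), error = function(e) rep(0, k - 1))
  drop(w_base + C %*% z)
}

#' @export
print.qpadm_result <- function(x, ...) {
  cat(sprintf("qpAdm: %s = %s\n", x$target,
              paste(sprintf("%.3f (+/- %.3f) %s", x$weights, x$se, x$sources),
                    collapse = " + ")))
  cat(sprintf("  chisq = %.3f, df = %d, p = %.4g, %d SNPs, %s\n",
              x$chisq, x$df, x$p_value, x$n_snps,
              if (x$plausible) "plausible" else "implausible"))
  invisible(x)
}

#' One-call qpAdm fit
#'
#' @inheritParams build_f4_system
#' @return A `qpadm_result`, see [fit_weights()].
#' @export
qpadm <- function(freqs, target, sources, right, block_size = 500) {
  fit_weights(build_f4_system(freqs, target, sources, right, block_size))
}

#' Distal model search over role-based source menus
#'
#' Mirrors the protocol of screening one candidate per ancestry role (e.g.
#' an early-farmer, a steppe and an East Asian source), fitting every
#' combination of one candidate per role, plus for each combination all
#' sub-models dropping one or two roles. The enumeration (including the
#' duplicated sub-models shared between combinations) is reported alongside
#' the deduplicated set that is actually fitted. Models are ranked by
#' p-value; a model is "nonrejected" at `p > alpha` and "plausible" when
#' all its weights lie in `[0, 1]`.
#'
#' @param freqs `group_freqs`.
#' @param target target label.
#' @param source_menu named list of candidate source vectors, one per role.
#' @param right right-population labels.
#' @param block_size jackknife block size.
#' @param alpha rejection level (default 0.05).
#' @return A `model_search_report` list: `models` data frame (one row per
#'   unique model, ranked by p), `n_enumerated`, `n_unique`,
#'   `n_nonrejected_plausible`, and the fitted `qpadm_result`s.
#' @export
model_search <- function(freqs, target, source_menu, right,
                         block_size = 500, alpha = 0.05) {
  if (!length(source_menu)) stop("empty source menu")
  roles <- names(source_menu)
  combos <- expand.grid(source_menu, stringsAsFactors = FALSE)
  n_roles <- length(roles)
  drop_sets <- list(integer(0))
  if (n_roles > 1)
    drop_sets <- c(drop_sets, lapply(seq_len(n_roles), function(i) i))
  if (n_roles > 2)
    drop_sets <- c(drop_sets, utils::combn(n_roles, 2, simplify = FALSE))
  enumerated <- list()
  for (ci in seq_len(nrow(combos))) {
    full <- unlist(combos[ci, ], use.names = TRUE)
    for (ds in drop_sets) {
      keep <- setdiff(seq_len(n_roles), ds)
      if (!length(keep)) next
      enumerated[[length(enumerated) + 1L]] <-
        stats::setNames(full[keep], roles[keep])
    }
  }
  keys <- vapply(enumerated, function(s) paste(sort(unname(s)), collapse = "+"), "")
  uniq <- !duplicated(keys)
  models <- enumerated[uniq]
  fits <- lapply(models, function(srcs) {
    tryCatch(qpadm(freqs, target, unname(srcs), right, block_size),
             error = function(e) e)
  })
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    key <- paste(sort(unname(models[[i]])), collapse = "+")
    roles <- paste(names(models[[i]]), collapse = "+")
    if (inherits(f, "error")) {
      # an unfittable model stays in the report with its failure
      return(data.frame(model = key, roles = roles,
                        n_sources = length(models[[i]]),
                        p_value = NA_real_, plausible = FALSE,
                        nonrejected = FALSE,
                        weights = paste("error:", conditionMessage(f)),
                        stringsAsFactors = FALSE))
    }
    data.frame(model = key, roles = roles,
               n_sources = length(f$sources),
               p_value = f$p_value,
               plausible = f$plausible,
               nonrejected = f$p_value > alpha,
               weights = paste(sprintf("%s=%.3f", f$sources, f$weights),
                               collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  # rank by p-value, preferring parsimony at ties; failures sort last
  ord <- order(-tab$p_value, tab$n_sources, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  structure(list(models = tab, fits = fits,
                 n_enumerated = length(enumerated),
                 n_unique = nrow(tab),
                 n_nonrejected_plausible = sum(tab$nonrejected & tab$plausible),
                 alpha = alpha),
            class = "model_search_report")
}

#' @export
print.model_search_report <- function(x, ...) {
  cat(sprintf("model search: %d enumerated fits (%d unique source sets), %d nonrejected & plausible at p > %g\n",
              x$n_enumerated, x$n_unique, x$n_nonrejected_plausible, x$alpha))
  print(utils::head(x$models[, c("model", "n_sources", "p_value", "plausible")], 5))
  invisible(x)
}
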