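#' PCA of reference genotypes with least-squares projection
#'
#' Principal components are fitted on a reference panel of (near-)complete
#' genotypes: per-SNP dosages are centred at their mean and scaled by
#' `sqrt(p(1-p))` with `p` the mean allele frequency (smartpca-style
#' normalisation), missing reference entries are mean-imputed for the fit
#' only, and the standardised matrix is decomposed by SVD. Sparse ancient
#' samples are then placed by least squares on their observed SNPs only
#' (the `lsqproject` semantics), so missingness does not drag projections
#' toward the origin.
#'
#' @name pca_projection
NULL

#' Fit a PCA model on a reference genotype matrix
#'
#' @param mat a [geno_matrix()] of reference samples (low missingness;
#'   missing entries are mean-imputed for the fit).
#' @param n_components number of components to retain.
#' @return A `pca_model`: per-SNP `center` and `scale`, `loadings`
#'   (SNP x component, column-orthonormal), `eigenvalues` (non-increasing),
#'   reference `scores`, `snp_ids`, `n_ref`.
#' @export
fit_pca <- function(mat, n_components = 10) {
  stopifnot(inherits(mat, "geno_matrix"))
  X <- mat$calls
  n <- nrow(X)
  if (n_components > min(dim(X)))
    stop("n_components exceeds matrix rank bound")
  center <- colMeans(X, na.rm = TRUE)
  center[is.nan(center)] <- 0
  eps <- 1 / (2 * n + 2)
  p_hat <- pmin(pmax(center / 2, eps), 1 - eps)
  scale <- sqrt(p_hat * (1 - p_hat))
  Xs <- sweep(X, 2, center)
  Xs[is.na(Xs)] <- 0
  Xs <- sweep(Xs, 2, scale, "/")
  sv <- svd(Xs, nu = n_components, nv = n_components)
  if (n_components > sum(sv$d > sv$d[1] * 1e-12))
    stop("n_components exceeds the numerical rank of the reference matrix")
  d <- sv$d[seq_len(n_components)]
  scores <- sv$u %*% diag(d, n_components)
  rownames(scores) <- mat$samples
  structure(list(center = center, scale = scale,
                 loadings = sv$v,
                 eigenvalues = d^2 / (n - 1),
                 scores = scores,
                 snp_ids = mat$snps$id, n_ref = n,
                 n_components = n_components),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d components on %d reference samples x %d SNPs\n",
              x$n_components, x$n_ref, length(x$snp_ids)))
  invisible(x)
}

#' Least-squares projection of a sparse sample onto a PCA model
#'
#' Coordinates minimise the squared distance between the sample's
#' standardised observed dosages and the loadings-spanned subspace,
#' restricted to the observed SNPs (normal equations on the observed-SNP
#' submatrix). With no missingness this equals the direct score
#' `t(loadings) %*% standardised`.
#'
#' @param model a `pca_model`.
#' @param calls named numeric vector of calls (0/1/2/NA) over the model's
#'   SNPs, or a [geno_matrix()] (each sample projected).
#' @param id sample identifier (vector form only).
#' @return A `projection` (list `id`, `coords`, `n_snps_used`, `flag`) or a
#'   list of projections for a matrix input.
#' @export
project_lsq <- function(model, calls, id = "sample") {
  stopifnot(inherits(model, "pca_model"))
  if (inherits(calls, "geno_matrix")) {
    idx <- match(model$snp_ids, calls$snps$id)
    if (anyNA(idx)) stop("sample matrix lacks some model SNPs")
    out <- lapply(seq_along(calls$samples), function(i)
      project_lsq(model, calls$calls[i, idx], calls$samples[i]))
    names(out) <- calls$samples
    return(out)
  }
  obs <- which(!is.na(calls))
  if (!length(obs)) stop("no observed SNP overlaps the model")
  A <- model$loadings[obs, , drop = FALSE]
  b <- (calls[obs] - model$center[obs]) / model$scale[obs]
  AtA <- crossprod(A)
  flag <- NA_character_
  coords <- tryCatch(drop(solve(AtA, crossprod(A, b))),
                     error = function(e) NULL)
  if (is.null(coords) || !all(is.finite(coords))) {
    # degenerate normal equations: least-norm solution via pseudo-inverse
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-10
    coords <- drop(sv$v[, pos, drop = FALSE] %*%
                     (crossprod(sv$u[, pos, drop = FALSE], b) / sv$d[pos]))
    flag <- "least_norm"
  }
  structure(list(id = id, coords = coords, n_snps_used = length(obs),
                 flag = flag),
            class = "projection")
}

#' Eigenvalue-scaled coordinates
#'
#' Multiplies the first `k` projected coordinates by their eigenvalues, the
#' scaling used before computing Euclidean distances in PC space.
#'
#' @param model a `pca_model`.
#' @param projection a `projection` (or bare coordinate vector).
#' @param k number of leading components (default 25, capped at the model).
#' @return Numeric vector of length `k`.
#' @export
scaled_coordinates <- function(model, projection, k = 25) {
  if (k < 1) stop("k must be >= 1")
  if (k > model$n_components)
    stop("k exceeds the number of fitted components")
  coords <- if (inherits(projection, "projection")) projection$coords
            else as.numeric(projection)
  coords[seq_len(k)] * model$eigenvalues[seq_len(k)]
}

#' Eigenvalue-scaled coordinates for many samples
#'
#' @param model a `pca_model`.
#' @param projections list of `projection`s (e.g. from [project_lsq()] on a
#'   matrix) or a score matrix with samples in rows.
#' @param k number of leading components.
#' @return Matrix (samples x k) of scaled coordinates.
#' @export
scaled_coordinate_matrix <- function(model, projections, k = 25) {
  if (is.matrix(projections)) {
    k <- min(k, ncol(projections))
    return(sweep(projections[, seq_len(k), drop = FALSE], 2,
                 model$eigenvalues[seq_len(k)], "*"))
  }
  out <- t(vapply(projections, function(p) scaled_coordinates(model, p, k),
                  numeric(k)))
  rownames(out) <- vapply(projections, `[[`, "", "id")
  out
}
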