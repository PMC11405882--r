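#' Standardise the contextual variable block
#'
#' Mean-centres every contextual variable and scales it to unit variance
#' (sample variance, denominator `n - 1`). Ordinal variables are treated as
#' numeric scores; body mass is log-transformed first by default, since it
#' spans several orders of magnitude and would otherwise act as a leverage
#' point.
#'
#' @param context A validated context tibble (see [read_context_table()]).
#' @param log_body_mass Natural-log transform body mass before scaling.
#' @return A numeric `n x 12` matrix with species ids as row names.
#' @export
standardize_context <- function(context, log_body_mass = TRUE) {
  meta <- context_variables()
  M <- as.matrix(context[, meta$variable])
  rownames(M) <- context$species_id
  if (log_body_mass) M[, "body_mass"] <- log(M[, "body_mass"])
  v <- apply(M, 2, stats::var)
  if (any(v <= .Machine$double.eps)) {
    stop("zero-variance contextual variable: ",
         paste(colnames(M)[v <= .Machine$double.eps], collapse = ", "),
         call. = FALSE)
  }
  scale(M)[, , drop = FALSE]
}

pls_sign_convention <- function(u, v) {
  # orient each dimension so the context loading of largest magnitude is
  # positive; deterministic across platforms
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  list(u = u, v = v)
}

new_pls_result <- function(u, v, d, x_scores, y_scores, phylogenetic,
                           p_values = NULL) {
  structure(
    list(x_loadings = u, y_loadings = v, singular_values = d,
         pct_sq_cov = 100 * d^2 / sum(d^2),
         x_scores = x_scores, y_scores = y_scores,
         p_values = p_values, phylogenetic = phylogenetic),
    class = "shape_pls"
  )
}

#' Two-block partial least squares
#'
#' Singular decomposition of the cross-covariance matrix between two blocks
#' of variables measured on the same specimens (typically Procrustes shape
#' coordinates and standardised contextual variables). Each pair of singular
#' vectors defines a pair of latent variables with maximal covariance
#' between their scores; the squared singular values, as percentages of
#' their sum, measure how much of the total squared cross-block covariance
#' each dimension accounts for.
#'
#' @param X `n x p` block (e.g. shape coordinates); column-centred
#'   internally.
#' @param Y `n x q` block (e.g. standardised context); column-centred
#'   internally. Row order must match `X`.
#' @param n_dims Number of dimensions to retain (default: full rank of the
#'   cross-covariance).
#' @return A `shape_pls` object with unit-norm `x_loadings` (`p x k`),
#'   `y_loadings` (`q x k`), `singular_values` (the cross-block covariances
#'   of the paired scores), `pct_sq_cov`, and species scores `x_scores`,
#'   `y_scores` (projections of the centred blocks).
#' @seealso [hierarchical_permutation_test()], [phylogenetic_two_block_pls()]
#' @export
two_block_pls <- function(X, Y, n_dims = NULL) {
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 3)
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y))) {
    stop("species (row) order differs between the two blocks", call. = FALSE)
  }
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  n <- nrow(Xc)
  S <- crossprod(Xc, Yc) / (n - 1)
  k_max <- min(dim(S), n - 1)
  if (is.null(n_dims)) n_dims <- k_max
  if (n_dims > k_max) stop("n_dims exceeds the rank of the cross-covariance",
                           call. = FALSE)
  sv <- svd(S)
  sg <- pls_sign_convention(sv$u[, seq_len(n_dims), drop = FALSE],
                            sv$v[, seq_len(n_dims), drop = FALSE])
  res <- new_pls_result(sg$u, sg$v, sv$d[seq_len(n_dims)],
                        Xc %*% sg$u, Yc %*% sg$v, phylogenetic = FALSE)
  res$pct_sq_cov <- 100 * res$singular_values^2 / sum(sv$d^2)
  res
}

#' @export
print.shape_pls <- function(x, ...) {
  cat(if (isTRUE(x$phylogenetic)) "Phylogenetic two-block PLS\n"
      else "Two-block PLS\n")
  k <- min(length(x$singular_values), 6)
  for (j in seq_len(k)) {
    cat(sprintf("  dim %d: singular value %.4g, %.1f%% of squared covariance%s\n",
                j, x$singular_values[j], x$pct_sq_cov[j],
                if (!is.null(x$p_values) && length(x$p_values) >= j)
                  sprintf(", p = %.3g", x$p_values[j]) else ""))
  }
  invisible(x)
}

# first singular value of the cross-covariance of two centred blocks
leading_sv <- function(Xc, Yc) {
  S <- crossprod(Xc, Yc) / (nrow(Xc) - 1)
  sqrt(max(eigen(crossprod(S), symmetric = TRUE, only.values = TRUE)$values, 0))
}

#' Hierarchical permutation test of PLS dimensions
#'
#' Tests each PLS dimension against a null hypothesis of no cross-block
#' association, conditional on the lower dimensions: for dimension `k`, both
#' blocks are deflated of the first `k - 1` observed singular vector pairs,
#' the rows of the deflated second block are permuted, and the test
#' statistic is the leading singular value of the deflated cross-covariance.
#' The p-value uses the `(b + 1)/(N + 1)` estimator.
#'
#' @param X,Y Blocks as in [two_block_pls()].
#' @param n_dims Number of dimensions to test.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Mandatory integer seed.
#' @return A numeric vector of per-dimension p-values.
#' @export
hierarchical_permutation_test <- function(X, Y, n_dims = 4, n_perm = 999, seed) {
  stopifnot(n_perm >= 99, !missing(seed))
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  n <- nrow(Xc)
  fit <- two_block_pls(X, Y)
  if (n_dims > length(fit$singular_values)) {
    stop("n_dims exceeds the rank of the cross-covariance", call. = FALSE)
  }
  p <- numeric(n_dims)
  with_seed(seed, {
    for (k in seq_len(n_dims)) {
      if (k > 1) {
        u <- fit$x_loadings[, seq_len(k - 1), drop = FALSE]
        v <- fit$y_loadings[, seq_len(k - 1), drop = FALSE]
        Xd <- Xc - (Xc %*% u) %*% t(u)
        Yd <- Yc - (Yc %*% v) %*% t(v)
      } else {
        Xd <- Xc; Yd <- Yc
      }
      obs <- leading_sv(Xd, Yd)
      hits <- 0L
      for (b in seq_len(n_perm)) {
        perm <- sample.int(n)
        if (leading_sv(Xd, Yd[perm, , drop = FALSE]) >= obs) hits <- hits + 1L
      }
      p[k] <- (hits + 1) / (n_perm + 1)
    }
  })
  p
}

#' Principal component analysis of shape coordinates
#'
#' Eigendecomposition of the covariance matrix of the column-centred data,
#' computed through [stats::prcomp()].
#'
#' @param X `n x p` matrix (e.g. Procrustes shape coordinates), or a
#'   `shape_gpa` object.
#' @return A list with `eigenvalues` (non-increasing, summing to the total
#'   variance), `eigenvectors` (columns, unit norm) and `scores`.
#' @export
shape_pca <- function(X) {
  if (inherits(X, "shape_gpa")) X <- X$shapes
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  list(eigenvalues = pc$sdev^2, eigenvectors = pc$rotation, scores = pc$x)
}
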