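#' Phylogenetic covariance matrix
#'
#' The Brownian-motion covariance of tip values: `C[i, j]` is the shared
#' branch length from the root to the most recent common ancestor of tips
#' `i` and `j`, and the diagonal holds root-to-tip depths (all equal for an
#' ultrametric tree).
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param species Optional character vector fixing the row/column order;
#'   must all be tips of the tree.
#' @return A symmetric positive definite `n x n` matrix with species
#'   dimnames.
#' @export
phylo_covariance <- function(tree, species = NULL) {
  C <- ape::vcv.phylo(tree)
  if (!is.null(species)) {
    missing_sp <- setdiff(species, rownames(C))
    if (length(missing_sp)) {
      stop("species absent from tree: ", paste(missing_sp, collapse = ", "),
           call. = FALSE)
    }
    C <- C[species, species]
  }
  C
}

# GLS (phylogenetic) mean of each column of X under covariance C
gls_mean <- function(X, Cinv) {
  one <- rep(1, nrow(X))
  drop(crossprod(one, Cinv %*% X)) / sum(Cinv)
}

#' Phylogenetic two-block partial least squares
#'
#' Two-block PLS of the evolutionary (rather than sample) cross-covariance:
#' blocks are centred on their generalised-least-squares means and the
#' cross-product is weighted by the inverse phylogenetic covariance matrix,
#' `R = X0' C^-1 Y0 / (n - 1)`, as in PGLS. Species scores are computed by
#' projecting the ordinary column-centred blocks onto the evolutionary
#' singular vectors (set `transformed_scores = TRUE` to project the
#' phylogenetically whitened blocks instead).
#'
#' @param X,Y Blocks as in [two_block_pls()], rows ordered as `C`.
#' @param C Phylogenetic covariance matrix from [phylo_covariance()];
#'   `C = diag(n)` reduces the analysis to the ordinary PLS.
#' @param n_dims Dimensions to retain.
#' @param transformed_scores Project whitened instead of raw centred blocks.
#' @return A `shape_pls` object with `phylogenetic = TRUE`.
#' @export
phylogenetic_two_block_pls <- function(X, Y, C, n_dims = NULL,
                                       transformed_scores = FALSE) {
  stopifnot(nrow(X) == nrow(Y), nrow(X) == nrow(C))
  n <- nrow(X)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("phylogenetic covariance matrix is singular", call. = FALSE))
  X0 <- sweep(X, 2, gls_mean(X, Cinv))
  Y0 <- sweep(Y, 2, gls_mean(Y, Cinv))
  R <- crossprod(X0, Cinv %*% Y0) / (n - 1)
  k_max <- min(dim(R), n - 1)
  if (is.null(n_dims)) n_dims <- k_max
  sv <- svd(R)
  sg <- pls_sign_convention(sv$u[, seq_len(n_dims), drop = FALSE],
                            sv$v[, seq_len(n_dims), drop = FALSE])
  if (transformed_scores) {
    W <- chol_inverse_sqrt(C)
    xs <- (W %*% X0) %*% sg$u
    ys <- (W %*% Y0) %*% sg$v
  } else {
    xs <- scale(X, scale = FALSE) %*% sg$u
    ys <- scale(Y, scale = FALSE) %*% sg$v
  }
  res <- new_pls_result(sg$u, sg$v, sv$d[seq_len(n_dims)], xs, ys,
                        phylogenetic = TRUE)
  res$pct_sq_cov <- 100 * res$singular_values^2 / sum(sv$d^2)
  res
}

# C^{-1/2} via Cholesky: t(solve(chol(C)))
chol_inverse_sqrt <- function(C) {
  t(backsolve(chol(C), diag(nrow(C))))
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' The ratio of the observed mean squared error of tip values around the
#' GLS (phylogenetic) mean to the mean squared error under the phylogenetic
#' covariance, scaled by its Brownian-motion expectation:
#' \deqn{K = \frac{(x-\hat a)'(x-\hat a) / (x-\hat a)' C^{-1} (x-\hat a)}
#'            {(\mathrm{tr}\,C - n / \mathbf{1}'C^{-1}\mathbf{1}) / (n-1)}}
#' `K` is about 1 for traits evolving by Brownian motion on the given tree,
#' below 1 when relatives resemble each other less than Brownian motion
#' predicts (as under convergence), and is invariant to affine transforms
#' of the trait.
#'
#' @param x Numeric trait vector, ordered as `C` (or named and reordered by
#'   `C`'s dimnames).
#' @param C Phylogenetic covariance matrix.
#' @return The scalar K.
#' @export
blomberg_k <- function(x, C) {
  n <- length(x)
  stopifnot(n >= 4, nrow(C) == n)
  if (!is.null(names(x)) && !is.null(rownames(C))) x <- x[rownames(C)]
  if (stats::var(x) <= .Machine$double.eps) {
    stop("Blomberg's K is undefined for a zero-variance trait", call. = FALSE)
  }
  Cinv <- solve(C)
  a_hat <- sum(Cinv %*% x) / sum(Cinv)
  r <- x - a_hat
  mse0 <- sum(r^2)
  mse <- drop(crossprod(r, Cinv %*% r))
  expected <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  (mse0 / mse) / expected
}

#' Simulate Brownian-motion traits on a tree
#'
#' Draws tip values of independent Brownian-motion characters with rate
#' `sigma2` (variance per unit branch length) and root state 0, using the
#' Cholesky factor of the phylogenetic covariance matrix.
#'
#' @param C Phylogenetic covariance matrix (or a tree, converted via
#'   [phylo_covariance()]).
#' @param n_traits Number of independent characters.
#' @param sigma2 Brownian rate.
#' @return `n_species x n_traits` matrix with species rownames.
#' @export
sim_bm_traits <- function(C, n_traits = 1, sigma2 = 1) {
  if (inherits(C, "phylo")) C <- phylo_covariance(C)
  L <- t(chol(C))
  Z <- matrix(stats::rnorm(nrow(C) * n_traits), nrow(C), n_traits)
  out <- sqrt(sigma2) * (L %*% Z)
  rownames(out) <- rownames(C)
  out
}

#' Simulate a pure-birth (Yule) tree forward in time
#'
#' Starts from a single lineage and lets each lineage split independently at
#' rate `birth` for a fixed `duration`; the expected number of surviving
#' lineages is `exp(birth * duration)`.
#'
#' @param birth Speciation rate.
#' @param duration Total simulation time.
#' @return Integer count of extant lineages at the end (the analytic check
#'   target) with attribute `"times"`, the ordered branching times.
#' @export
sim_yule_count <- function(birth, duration) {
  t <- 0; n <- 1L
  times <- numeric(0)
  repeat {
    wait <- stats::rexp(1, rate = birth * n)
    if (t + wait > duration) break
    t <- t + wait
    times <- c(times, t)
    n <- n + 1L
  }
  structure(n, times = times)
}
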