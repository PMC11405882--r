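test_that("context standardisation centres, scales, and rejects degenerate columns", {
  ctx <- context_fixture(n = 8)
  Z <- standardize_context(ctx)
  expect_equal(dim(Z), c(8, 12))
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_equal(unname(apply(Z, 2, var)), rep(1, 12), tolerance = 1e-12)
  # sample-variance convention: a 1,2,3 column maps to -1, 0, 1
  ctx3 <- context_fixture(n = 3)
  ctx3$agility <- c(1, 2, 3)
  expect_equal(unname(standardize_context(ctx3)[, "agility"]), c(-1, 0, 1))
  flat <- ctx; flat$fossorial <- 2
  expect_error(standardize_context(flat), "fossorial")
  # log transform changes the body-mass column, not the ordinals
  Z2 <- standardize_context(ctx, log_body_mass = FALSE)
  expect_false(isTRUE(all.equal(Z[, "body_mass"], Z2[, "body_mass"])))
  expect_equal(Z[, "agility"], Z2[, "agility"])
})

test_that("two-block PLS maximises cross-block covariance and partitions it", {
  tb <- toy_blocks(n = 6, p = 4, q = 3)
  fit <- two_block_pls(tb$X, tb$Y)
  # leading singular value equals the constrained numeric maximum
  expect_equal(fit$singular_values[1], pls_sv1_numeric(tb$X, tb$Y),
               tolerance = 1e-6)
  # loadings orthonormal, singular values non-increasing
  expect_equal(crossprod(fit$x_loadings), diag(ncol(fit$x_loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(crossprod(fit$y_loadings), diag(ncol(fit$y_loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(fit$singular_values) <= 1e-12))
  # summed squared singular values = squared Frobenius norm of cross-cov
  Xc <- scale(tb$X, scale = FALSE); Yc <- scale(tb$Y, scale = FALSE)
  S <- crossprod(Xc, Yc) / (nrow(Xc) - 1)
  expect_equal(sum(fit$singular_values^2), sum(S^2), tolerance = 1e-10)
  expect_equal(sum(fit$pct_sq_cov), 100, tolerance = 1e-8)
  # scores are projections with covariance equal to the singular value
  expect_equal(cov(fit$x_scores[, 1], fit$y_scores[, 1]),
               fit$singular_values[1], tolerance = 1e-10)
  # sign convention: dominant context loading positive
  expect_gt(fit$y_loadings[which.max(abs(fit$y_loadings[, 1])), 1], 0)
})

test_that("two-block PLS recovers a planted factor and nulls orthogonal blocks", {
  set.seed(14)
  # whitened X: the cross-covariance with X a + noise points along a
  X <- matrix(rnorm(30 * 20), 30, 20)
  Xc <- scale(X, scale = FALSE)
  X <- Xc %*% solve(chol(cov(Xc)))
  a <- rnorm(20); a <- a / sqrt(sum(a^2))
  Y <- cbind(X %*% a + rnorm(30, sd = 0.05))
  fit <- two_block_pls(X, Y)
  expect_gt(abs(cor(fit$x_loadings[, 1], a)), 0.99)

  # constructed zero cross-covariance: all singular values vanish
  Xc <- scale(X[, 1:5], scale = FALSE)
  Yr <- matrix(rnorm(30 * 3), 30, 3)
  Yr <- Yr - Xc %*% solve(crossprod(Xc), crossprod(Xc, Yr))  # residualise
  fit0 <- two_block_pls(X[, 1:5], Yr)
  expect_lt(max(fit0$singular_values), 1e-10)

  expect_error(two_block_pls(X[1:5, ], Y), "row")
})

test_that("hierarchical permutation p-values match exhaustive enumeration and edge cases", {
  # degenerate Y: statistic invariant under permutation, p = 1 everywhere
  set.seed(3)
  X <- matrix(rnorm(24), 6, 4)
  Yc <- matrix(1, 6, 2)
  expect_error(two_block_pls(X, Yc * 0), NA)  # centred-constant Y is rank 0
  p_const <- hierarchical_permutation_test(X, cbind(1:6 * 0 + 5, 1:6 * 0 + 2) +
                                             0, n_dims = 1, n_perm = 99,
                                           seed = 1)
  expect_equal(p_const, 1)

  # n = 5 species: exhaustive permutation null vs sampled p
  tb <- toy_blocks(n = 5, p = 3, q = 2, seed = 9)
  Xc <- scale(tb$X, scale = FALSE); Yc2 <- scale(tb$Y, scale = FALSE)
  sv1 <- function(Xm, Ym) {
    S <- crossprod(Xm, Ym) / (nrow(Xm) - 1)
    svd(S)$d[1]
  }
  obs <- sv1(Xc, Yc2)
  perms <- all_perms(5)
  null_svs <- apply(perms, 1, function(pr) sv1(Xc, Yc2[pr, , drop = FALSE]))
  p_exact <- mean(null_svs >= obs - 1e-12)
  p_sampled <- hierarchical_permutation_test(tb$X, tb$Y, n_dims = 1,
                                             n_perm = 999, seed = 42)[1]
  se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(p_sampled - p_exact), 3 * se + 2 / 999)

  # strong planted factor: dimension 1 highly significant
  set.seed(15)
  X2 <- matrix(rnorm(30 * 10), 30, 10)
  a <- rnorm(10); a <- a / sqrt(sum(a^2))
  Y2 <- cbind(X2 %*% a + rnorm(30, sd = 0.02), rnorm(30))
  p <- hierarchical_permutation_test(X2, Y2, n_dims = 2, n_perm = 999, seed = 5)
  expect_lte(p[1], 0.01)
  expect_gt(p[2], 0.05)

  expect_error(hierarchical_permutation_test(tb$X, tb$Y, n_dims = 10,
                                             n_perm = 99, seed = 1), "rank")
})

test_that("phylogenetic covariance matches the tree and the patristic oracle", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_covariance(tr, c("A", "B", "C"))
  expect_equal(unname(C),
               rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))
  # star tree: C = t I
  star <- ape::read.tree(text = "(A:1.5,B:1.5,C:1.5,D:1.5);")
  expect_equal(unname(phylo_covariance(star)), 1.5 * diag(4))
  # random tree: C[i,j] = (depth_i + depth_j - d_patristic(i,j)) / 2
  tree <- simulate_tree(simulation_config(seed = 8, n_species = 20, n_focal = 8))
  C2 <- phylo_covariance(tree)
  pat <- ape::cophenetic.phylo(tree)[rownames(C2), rownames(C2)]
  depths <- diag(C2)
  expect_equal(C2, (outer(depths, depths, `+`) - pat) / 2, tolerance = 1e-10)
  expect_error(phylo_covariance(tr, c("A", "Z")), "absent")
})

test_that("phylogenetic PLS reduces to ordinary PLS for C proportional to identity", {
  tb <- toy_blocks(n = 8, p = 5, q = 3, seed = 21)
  ord <- two_block_pls(tb$X, tb$Y)
  phy <- phylogenetic_two_block_pls(tb$X, tb$Y, diag(8))
  expect_equal(phy$singular_values, ord$singular_values, tolerance = 1e-10)
  expect_equal(phy$x_loadings, ord$x_loadings, tolerance = 1e-10)
  expect_equal(phy$y_loadings, ord$y_loadings, tolerance = 1e-10)
  # scale invariance of the directions
  phy2 <- phylogenetic_two_block_pls(tb$X, tb$Y, 3.7 * diag(8))
  expect_equal(phy2$x_loadings, ord$x_loadings, tolerance = 1e-10)
  expect_error(phylogenetic_two_block_pls(tb$X, tb$Y, matrix(1, 8, 8)),
               "singular")
})

test_that("phylogenetic PLS matches a direct evaluation of the GLS cross-covariance", {
  set.seed(33)
  tree <- ape::rcoal(6)
  C <- phylo_covariance(tree)
  X <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(rownames(C), NULL))
  Y <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(rownames(C), NULL))
  # independent element-by-element evaluation
  Ci <- solve(C)
  one <- rep(1, 6)
  aX <- drop(t(one) %*% Ci %*% X) / drop(t(one) %*% Ci %*% one)
  aY <- drop(t(one) %*% Ci %*% Y) / drop(t(one) %*% Ci %*% one)
  R <- matrix(0, 4, 3)
  for (i in 1:4) for (j in 1:3) {
    R[i, j] <- drop(t(X[, i] - aX[i]) %*% Ci %*% (Y[, j] - aY[j])) / 5
  }
  fit <- phylogenetic_two_block_pls(X, Y, C)
  expect_equal(fit$singular_values, svd(R)$d[1:length(fit$singular_values)],
               tolerance = 1e-10)
  expect_equal(abs(cor(fit$x_loadings[, 1], svd(R)$u[, 1])), 1,
               tolerance = 1e-10)
})

test_that("PCA of shapes conserves variance and matches the SVD route", {
  set.seed(4)
  X <- matrix(rnorm(20), 5, 4)
  pc <- shape_pca(X)
  expect_equal(sum(pc$eigenvalues), sum(apply(X, 2, var)), tolerance = 1e-10)
  sv <- svd(scale(X, scale = FALSE))
  expect_equal(unname(abs(pc$scores[, 1])), abs(sv$u[, 1] * sv$d[1]),
               tolerance = 1e-10)
  # collinear data: a single non-zero eigenvalue
  line <- outer(1:5, c(1, 2, -1, 0.5))
  pcl <- shape_pca(line)
  expect_gt(pcl$eigenvalues[1], 1e-8)
  expect_lt(pcl$eigenvalues[2], 1e-12)
})

test_that("Blomberg's K has its closed-form and invariance properties", {
  # star tree: K = 1 exactly for any non-constant trait
  starC <- 2 * diag(6)
  rownames(starC) <- colnames(starC) <- sprintf("s%d", 1:6)
  set.seed(9)
  x <- rnorm(6)
  expect_equal(blomberg_k(x, starC), 1, tolerance = 1e-12)
  # affine invariance
  tree <- simulate_tree(simulation_config(seed = 10, n_species = 12, n_focal = 6))
  C <- phylo_covariance(tree)
  y <- rnorm(12)
  expect_equal(blomberg_k(y, C), blomberg_k(-2.5 * y + 7, C), tolerance = 1e-10)
  expect_error(blomberg_k(rep(1, 12), C), "zero-variance")
})

test_that("Blomberg's K agrees with the independent phylosig implementation", {
  skip_if_not_installed("phytools")
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:0.5,D:0.5):1.5);")
  x <- c(A = 1.2, B = 0.8, C = -0.4, D = 2.1)
  C <- phylo_covariance(tree, names(x))
  k_ref <- unname(phytools::phylosig(tree, x, method = "K"))
  expect_equal(blomberg_k(x, C), as.numeric(k_ref), tolerance = 1e-8)
})

test_that("K averages near 1 for Brownian traits and BM tip variance scales with depth", {
  tree <- simulate_tree(simulation_config(seed = 13))
  C <- phylo_covariance(tree)
  set.seed(31)
  ks <- replicate(200, blomberg_k(drop(sim_bm_traits(C)), C))
  expect_gt(mean(ks), 0.85)
  expect_lt(mean(ks), 1.15)
  # tip variance across replicates equals sigma2 x depth (unit depth here)
  tips <- replicate(400, sim_bm_traits(C, sigma2 = 0.5)[1, 1])
  expect_equal(var(tips), 0.5, tolerance = 0.2)
})
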