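# 6-species toy: focal f1, f2 (f3 unpaired focal), nonfocal a1, a2, b1
toy_pairing <- function() {
  as_analogue_pairing(tibble::tibble(
    focal = c("f1", "f2", "f3"),
    analogue = c("a1", "a2", NA)))
}

toy_D <- function(seed = 2) {
  set.seed(seed)
  sp <- c("f1", "f2", "f3", "a1", "a2", "b1")
  toy_distance_matrix(runif(15, 0.1, 1), sp)
}

test_that("pair-type averages partition all pairs and match hand enumeration", {
  D <- toy_D()
  pr <- toy_pairing()
  avg <- pair_type_averages(D, pr)
  expect_equal(sum(avg$n_pairs), 6 * 5 / 2)
  # hand-enumerated classes
  analogue <- c(D["f1", "a1"], D["f2", "a2"])
  nonanalogue <- c(D["f1", "a2"], D["f1", "b1"], D["f2", "a1"], D["f2", "b1"],
                   D["f3", "a1"], D["f3", "a2"], D["f3", "b1"])
  within_f <- c(D["f1", "f2"], D["f1", "f3"], D["f2", "f3"])
  within_n <- c(D["a1", "a2"], D["a1", "b1"], D["a2", "b1"])
  expect_equal(avg$mean, vapply(list(analogue, nonanalogue, within_f, within_n),
                                mean, numeric(1)))
  expect_equal(avg$median,
               vapply(list(analogue, nonanalogue, within_f, within_n),
                      median, numeric(1)))
  expect_equal(avg$n_pairs, c(2L, 7L, 3L, 3L))
  expect_equal(attr(avg, "excess_pct"),
               100 * (mean(nonanalogue) / mean(analogue) - 1))

  # constant distances: all four means equal, excess zero
  Dc <- toy_distance_matrix(rep(0.4, 15), rownames(D))
  avg_c <- pair_type_averages(Dc, pr)
  expect_equal(avg_c$mean, rep(0.4, 4))
  expect_equal(attr(avg_c, "excess_pct"), 0)
  # excess is invariant to a global rescaling of distances
  avg_s <- pair_type_averages(10 * D, pr)
  expect_equal(attr(avg_s, "excess_pct"), attr(avg, "excess_pct"))

  # a class emptied by species removal is an error naming the class
  D4 <- D[c("f1", "f2", "f3", "a1"), c("f1", "f2", "f3", "a1")]
  expect_error(pair_type_averages(D4, pr), "within_nonfocal")
})

test_that("affiliation permutation test matches exhaustive enumeration and edge cases", {
  D <- toy_D(seed = 4)
  pr <- toy_pairing()
  # exhaustive null: all relabellings of the 3 non-focal species
  sp <- rownames(D)
  focal <- c("f1", "f2", "f3"); nonfocal <- c("a1", "a2", "b1")
  A <- matrix(FALSE, 3, 3, dimnames = list(focal, nonfocal))
  A["f1", "a1"] <- TRUE; A["f2", "a2"] <- TRUE
  Dfn <- D[focal, nonfocal]
  stat <- function(M) mean(M[!A]) - mean(M[A])
  obs <- stat(Dfn)
  perms <- all_perms(3)
  null_stats <- apply(perms, 1, function(pr_) stat(Dfn[, pr_]))
  p_exact <- mean(null_stats >= obs - 1e-12)
  res <- convergence_permutation_test(D, pr, n_perm = 999, seed = 31)
  se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 2 / 999)

  # constant distances carry no affiliation signal
  Dc <- toy_distance_matrix(rep(0.4, 15), sp)
  expect_equal(convergence_permutation_test(Dc, pr, n_perm = 99,
                                            seed = 1)$p_value, 1)
  one_pair <- as_analogue_pairing(tibble::tibble(focal = "f1", analogue = "a1"))
  expect_error(convergence_permutation_test(D, one_pair, n_perm = 99, seed = 1),
               "at least 2")
  # determinism under a fixed seed
  expect_identical(convergence_permutation_test(D, pr, n_perm = 199, seed = 7),
                   convergence_permutation_test(D, pr, n_perm = 199, seed = 7))
})

test_that("Wheatsheaf index matches hand computation and penalises relatedness", {
  sp <- c("f1", "f2", "a1", "a2")
  pr <- as_analogue_pairing(tibble::tibble(focal = c("f1", "f2"),
                                           analogue = c("a1", "a2")))
  D <- toy_distance_matrix(c(0.5, 0.2, 0.6, 0.7, 0.3, 0.4), sp)
  # uncorrected, all-pairs denominator: mean(all) / mean(analogue)
  m_analogue <- mean(c(D["f1", "a1"], D["f2", "a2"]))
  expect_equal(wheatsheaf_index(D, pr),
               mean(D[upper.tri(D)]) / m_analogue)
  m_nonanalogue <- mean(c(D["f1", "a2"], D["f2", "a1"]))
  expect_equal(wheatsheaf_index(D, pr, denominator = "nonanalogue"),
               m_nonanalogue / m_analogue)
  # equal distances: index exactly 1
  Dc <- toy_distance_matrix(rep(0.3, 6), sp)
  expect_equal(wheatsheaf_index(Dc, pr), 1)

  # corrected form: hand evaluation of the BM-distance penalty
  tree <- ape::read.tree(text = "((f1:1,f2:1):1,(a1:1,a2:1):1);")
  C <- phylo_covariance(tree, sp)
  idx <- utils::combn(4, 2)
  w <- sqrt(diag(C)[idx[1, ]] + diag(C)[idx[2, ]] -
              2 * C[cbind(idx[1, ], idx[2, ])])
  w <- w / mean(w)
  dvals <- D[cbind(idx[1, ], idx[2, ])] / w
  is_analogue <- apply(idx, 2, function(ij)
    all(sort(sp[ij]) %in% c("f1", "a1")) || all(sort(sp[ij]) %in% c("f2", "a2")))
  expect_equal(wheatsheaf_index(D, pr, C = C, corrected = TRUE),
               mean(dvals) / mean(dvals[is_analogue]))
  # the corrected index differs from the uncorrected one on an uneven tree
  expect_false(isTRUE(all.equal(wheatsheaf_index(D, pr, C = C, corrected = TRUE),
                                wheatsheaf_index(D, pr))))
  expect_error(wheatsheaf_index(D, pr, corrected = TRUE), "needs C")
  expect_error(wheatsheaf_index(Dc * 0, pr), "undefined")
})

test_that("subspace removal obeys projection identities", {
  set.seed(6)
  X <- matrix(rnorm(10 * 8), 10, 8)
  U <- qr.Q(qr(matrix(rnorm(8 * 3), 8, 3)))
  resid <- project_out_dimensions(X, U)
  # residual orthogonal to every loading
  expect_lt(max(abs(resid %*% U)), 1e-10)
  # k = 0 leaves (centred) distances unchanged
  expect_equal(as.matrix(dist(project_out_dimensions(X, U[, 0]))),
               as.matrix(dist(X)), tolerance = 1e-10, ignore_attr = TRUE)
  # loadings spanning the whole space null all distances
  Ufull <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
  expect_lt(max(dist(project_out_dimensions(X, Ufull))), 1e-8)
  # Pythagoras: within + residual squared distances = full squared distances
  Xc <- scale(X, scale = FALSE)
  d_full2 <- as.matrix(dist(Xc))^2
  d_within2 <- as.matrix(dist(Xc %*% U))^2
  d_resid2 <- as.matrix(dist(resid))^2
  expect_equal(d_within2 + d_resid2, d_full2, tolerance = 1e-8)
  # non-orthonormal loadings rejected unless reorthonormalisation requested
  expect_error(project_out_dimensions(X, U * 2), "orthonormal")
  expect_equal(project_out_dimensions(X, U * 2, reorthonormalise = TRUE),
               resid, tolerance = 1e-10)
})

test_that("the subspace contrast isolates a planted convergence signal", {
  st <- small_study(seed = 17, n_species = 20, n_focal = 10)
  fit <- gpa(st$landmarks)
  pls <- two_block_pls(fit$shapes, standardize_context(st$context))
  sc <- subspace_convergence_contrast(fit, pls$x_loadings[, 1:4, drop = FALSE],
                                      st$pairing, n_perm = 99, seed = 21)
  expect_s3_class(sc$within, "convergence_report")
  expect_s3_class(sc$residual, "convergence_report")
  expect_gt(sc$within$excess_pct, sc$residual$excess_pct)
  expect_lte(sc$within$p_value, 0.05)
})
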