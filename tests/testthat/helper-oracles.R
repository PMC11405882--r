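# independent oracles and small fixture builders used across test files

# all n! permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1)))
  }
  out
}

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# brute-force minimal superposition distance over a refined quaternion grid
quaternion_grid_distance <- function(a, b, allow_reflection = FALSE) {
  normalise <- function(p) {
    p <- sweep(p, 2, colMeans(p)); p / sqrt(sum(p^2))
  }
  A <- normalise(a); B <- normalise(b)
  eval_best <- function(M) {
    set.seed(99)
    qs <- matrix(rnorm(4 * 4000), ncol = 4)
    best <- c(Inf, 0, 0, 0, 0)
    score <- function(q) {
      R <- quat_to_rot(q)
      2 - 2 * sum(R * M)
    }
    for (i in seq_len(nrow(qs))) {
      s <- score(qs[i, ])
      if (s < best[1]) best <- c(s, qs[i, ] / sqrt(sum(qs[i, ]^2)))
    }
    for (sigma in c(0.3, 0.1, 0.03, 0.01, 0.003, 0.001)) {
      cand <- matrix(rnorm(4 * 1500, sd = sigma), ncol = 4) +
        matrix(best[2:5], 1500, 4, byrow = TRUE)
      for (i in seq_len(nrow(cand))) {
        s <- score(cand[i, ])
        if (s < best[1]) best <- c(s, cand[i, ] / sqrt(sum(cand[i, ]^2)))
      }
    }
    best[1]
  }
  d2 <- eval_best(crossprod(A, B))
  if (allow_reflection) {
    Aref <- A; Aref[, 1] <- -Aref[, 1]
    d2 <- min(d2, eval_best(crossprod(Aref, B)))
  }
  sqrt(max(d2, 0))
}

# TPS bending energy by the interpolation route: solve the full spline
# system for the mapping reference -> target and evaluate w' K w per
# coordinate (independent of the block-inverse bending-energy matrix)
tps_energy_interpolation <- function(reference, target) {
  k <- nrow(reference)
  r <- as.matrix(dist(reference))
  K <- -r
  Q <- cbind(1, reference)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 4, 4)))
  total <- 0
  for (d in 1:3) {
    sol <- solve(L, c(target[, d], rep(0, 4)))
    w <- sol[seq_len(k)]
    total <- total + drop(crossprod(w, K %*% w))
  }
  total
}

# leading cross-covariance singular value by constrained numeric
# maximisation of cov(Xa, Yb) over unit vectors, multiple starts
pls_sv1_numeric <- function(X, Y, n_starts = 12) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  S <- crossprod(Xc, Yc) / (nrow(X) - 1)
  p <- nrow(S); q <- ncol(S)
  obj <- function(par) {
    a <- par[1:p]; b <- par[(p + 1):(p + q)]
    -drop(a %*% S %*% b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  }
  set.seed(7)
  best <- Inf
  for (s in seq_len(n_starts)) {
    par0 <- rnorm(p + q)
    fit <- optim(par0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  abs(best)
}

# tiny 6-point scheme with one sliding semilandmark on a straight segment
line_scheme <- function() {
  structure(
    list(n_points = 6L, n_anatomical = 5L, n_semilandmarks = 1L,
         roles = c(rep("anatomical", 5), "semilandmark"),
         curve_id = c(rep("none", 5), "seg"),
         curves = list(list(curve_id = "seg", path = c(1L, 6L, 2L),
                            sliders = 6L, closed = FALSE))),
    class = "landmark_scheme")
}

line_reference <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1),
        c(0.5, 0.05, 0))
}

# deterministic small aligned shape matrix + context for PLS tests
toy_blocks <- function(n = 6, p = 4, q = 3, seed = 11) {
  set.seed(seed)
  list(X = matrix(rnorm(n * p), n, p), Y = matrix(rnorm(n * q), n, q))
}

# small synthetic distance matrix with named species
toy_distance_matrix <- function(values, species) {
  n <- length(species)
  D <- matrix(0, n, n, dimnames = list(species, species))
  D[lower.tri(D)] <- values
  D <- D + t(D)
  D
}

small_study <- function(seed = 1, n_species = 14, n_focal = 7, ...) {
  simulate_study(simulation_config(seed = seed, n_species = n_species,
                                   n_focal = n_focal, ...))
}

context_fixture <- function(n = 6, seed = 3) {
  set.seed(seed)
  meta <- context_variables()
  ctx <- tibble::tibble(species_id = sprintf("sp%02d", seq_len(n)))
  for (i in seq_len(nrow(meta))) {
    v <- meta$variable[i]
    ctx[[v]] <- if (v == "body_mass") exp(runif(n, 3, 9))
                else sample(seq(meta$min_level[i], meta$max_level[i]), n,
                            replace = TRUE)
  }
  # ensure non-degenerate columns
  for (i in seq_len(nrow(meta))[-1]) {
    v <- meta$variable[i]
    if (var(ctx[[v]]) == 0) ctx[[v]][1] <- ctx[[v]][1] %% meta$max_level[i] + 1
  }
  validate_context_table(ctx)
}
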