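#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of all points to their
#' centroid; the scale measure removed by Procrustes superimposition.
#'
#' @param points A `k x 3` coordinate matrix.
#' @return A positive scalar.
#' @export
centroid_size <- function(points) {
  ctr <- sweep(points, 2, colMeans(points))
  sqrt(sum(ctr^2))
}

# centre and scale to unit centroid size
normalise_config <- function(points) {
  ctr <- sweep(points, 2, colMeans(points))
  cs <- sqrt(sum(ctr^2))
  if (cs <= .Machine$double.eps) {
    stop("degenerate configuration: all points coincident", call. = FALSE)
  }
  list(points = ctr / cs, size = cs)
}

#' Optimal superimposition of two configurations
#'
#' Centres both configurations, scales them to unit centroid size, and finds
#' the orthogonal map (rotation, or rotation-plus-reflection when
#' `allow_reflection = TRUE`) of the first that minimises the summed squared
#' differences to the second. The residual distance is the partial
#' Procrustes distance between the two shapes.
#'
#' @param a,b `k x 3` coordinate matrices with equal point counts.
#' @param allow_reflection Permit maps with determinant -1 (needed when the
#'   sample mixes left and right sides).
#' @return A list with `rotation` (3 x 3 orthogonal matrix applied to the
#'   normalised `a`), `distance` (residual Procrustes distance),
#'   `reflected` (logical).
#' @export
optimal_superposition <- function(a, b, allow_reflection = FALSE) {
  stopifnot(nrow(a) == nrow(b), ncol(a) == 3, ncol(b) == 3)
  na <- normalise_config(a)$points
  nb <- normalise_config(b)$points
  sv <- svd(crossprod(na, nb))
  rot <- sv$u %*% t(sv$v)
  d <- sv$d
  reflected <- det(rot) < 0
  if (!allow_reflection && reflected) {
    # flip the direction of least variance back to a proper rotation
    sv$u[, 3] <- -sv$u[, 3]
    d[3] <- -d[3]
    rot <- sv$u %*% t(sv$v)
    reflected <- FALSE
  }
  dist2 <- max(0, 2 - 2 * sum(d))
  list(rotation = rot, distance = sqrt(dist2), reflected = reflected)
}

#' Generalised Procrustes Analysis
#'
#' Iteratively removes location, scale and orientation (optionally
#' reflection) from a sample of configurations by least-squares alignment to
#' an evolving consensus. Accepts either a long landmark tibble or an
#' `n x k x 3` array.
#'
#' @param data Long landmark tibble (see [read_landmarks()]) or array.
#' @param allow_reflection Allow mirroring during alignment (default `TRUE`;
#'   samples mixing left and right sides require it).
#' @param tol Convergence tolerance on the root-mean-square change of the
#'   consensus between iterations.
#' @param max_iter Maximum number of alignment sweeps.
#' @param scheme Optional `landmark_scheme` for validation when `data` is a
#'   tibble.
#' @return An object of class `shape_gpa`: list with
#'   \describe{
#'     \item{aligned}{`n x k x 3` array of Procrustes shape coordinates
#'       (centred, unit centroid size, rotated to the consensus)}
#'     \item{shapes}{`n x 3k` matrix of the same coordinates, one row per
#'       specimen (x, y, z interleaved per point)}
#'     \item{consensus}{`k x 3` mean shape (coordinate-wise mean of
#'       `aligned`)}
#'     \item{centroid_sizes}{named numeric vector, input units}
#'     \item{reflected}{named logical vector}
#'     \item{iterations, converged}{iteration count and convergence flag}
#'   }
#' @examples
#' study <- simulate_study(simulation_config(seed = 1, n_species = 8))
#' fit <- gpa(study$landmarks)
#' fit
#' @export
gpa <- function(data, allow_reflection = TRUE, tol = 1e-9, max_iter = 100,
                scheme = NULL) {
  arr <- if (is.array(data) && length(dim(data)) == 3) data
         else landmarks_to_array(data, scheme)
  n <- dim(arr)[1]; k <- dim(arr)[2]
  if (n < 2) stop("GPA needs at least 2 configurations", call. = FALSE)
  ids <- dimnames(arr)[[1]]
  sizes <- numeric(n)
  norm <- array(0, dim(arr), dimnames = dimnames(arr))
  for (i in seq_len(n)) {
    nc <- normalise_config(arr[i, , ])
    norm[i, , ] <- nc$points
    sizes[i] <- nc$size
  }
  names(sizes) <- ids
  reflected <- setNames(logical(n), ids)

  # initial consensus: first configuration; record reflection at first alignment
  consensus <- norm[1, , ]
  for (i in seq_len(n)) {
    os <- optimal_superposition(norm[i, , ], consensus, allow_reflection)
    reflected[i] <- os$reflected
    norm[i, , ] <- norm[i, , ] %*% os$rotation
  }
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    consensus <- apply(norm, c(2, 3), mean)
    ref <- normalise_config(consensus)$points
    for (i in seq_len(n)) {
      os <- optimal_superposition(norm[i, , ], ref, allow_reflection)
      norm[i, , ] <- norm[i, , ] %*% os$rotation
    }
    new_consensus <- apply(norm, c(2, 3), mean)
    delta <- sqrt(mean((new_consensus - consensus)^2))
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  consensus <- apply(norm, c(2, 3), mean)
  structure(
    list(aligned = norm, shapes = flatten_shapes(norm), consensus = consensus,
         centroid_sizes = sizes, reflected = reflected,
         iterations = iter, converged = converged,
         allow_reflection = allow_reflection),
    class = "shape_gpa"
  )
}

#' @export
print.shape_gpa <- function(x, ...) {
  cat("Generalised Procrustes Analysis:", dim(x$aligned)[1], "configurations,",
      dim(x$aligned)[2], "points\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  mirroring:", if (x$allow_reflection) "allowed" else "disallowed",
      "| reflected specimens:", sum(x$reflected), "\n")
  invisible(x)
}

#' Pairwise Procrustes distances
#'
#' Euclidean distances between the aligned unit-size shape coordinate
#' vectors of all pairs of specimens in a common superimposition.
#'
#' @param alignment A `shape_gpa` object, or an `n x p` matrix of aligned
#'   shape coordinates (rows = specimens).
#' @return A symmetric `n x n` distance matrix with zero diagonal.
#' @export
pairwise_procrustes_distances <- function(alignment) {
  shapes <- if (inherits(alignment, "shape_gpa")) alignment$shapes else alignment
  as.matrix(stats::dist(shapes))
}
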