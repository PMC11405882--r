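# classify all unordered species pairs into the four pair types:
# 1 focal-analogue, 2 focal-nonanalogue (non-focal), 3 focal-focal,
# 4 nonfocal-nonfocal. An unpaired focal species contributes to types 2
# and 3 only.
pair_types <- function(species, pairing) {
  is_focal <- species %in% pairing$focal_set
  idx <- utils::combn(length(species), 2)
  type <- integer(ncol(idx))
  for (p in seq_len(ncol(idx))) {
    i <- idx[1, p]; j <- idx[2, p]
    fi <- is_focal[i]; fj <- is_focal[j]
    if (fi && fj) type[p] <- 3L
    else if (!fi && !fj) type[p] <- 4L
    else {
      f <- species[if (fi) i else j]
      a <- species[if (fi) j else i]
      type[p] <- if (a %in% pairing$analogue_map[[f]]) 1L else 2L
    }
  }
  tibble::tibble(i = idx[1, ], j = idx[2, ],
                 species_i = species[idx[1, ]], species_j = species[idx[2, ]],
                 type = type)
}

#' Average Procrustes distances by pair type
#'
#' Partitions all unordered species pairs into four disjoint types --
#' (1) focal species with their designated analogues, (2) focal species
#' with non-analogue non-focal species, (3) focal-focal and (4)
#' nonfocal-nonfocal pairs -- and averages the pairwise shape distances
#' within each type. Convergence is indicated when type-1 distances are
#' smaller than the other three. Focal species without an analogue enter
#' types 2 and 3 only.
#'
#' @param D Symmetric distance matrix with species dimnames (e.g. from
#'   [pairwise_procrustes_distances()]).
#' @param pairing An `analogue_pairing`.
#' @return An object of class `pair_type_averages`: tibble with one row per
#'   pair type (`type`, `label`, `mean`, `median`, `n_pairs`) plus
#'   attributes `excess_pct` = `100 * (mean_nonanalogue / mean_analogue - 1)`
#'   and `excess_pct_median`.
#' @export
pair_type_averages <- function(D, pairing) {
  species <- rownames(D)
  stopifnot(!is.null(species), isSymmetric(unname(D)))
  pt <- pair_types(species, pairing)
  d <- D[cbind(pt$i, pt$j)]
  labels <- c("analogue", "nonanalogue", "within_focal", "within_nonfocal")
  if (length(unique(pt$type)) < 4) {
    stop("empty pair class: ", paste(labels[setdiff(1:4, unique(pt$type))],
                                     collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    type = 1:4,
    label = labels,
    mean = vapply(1:4, function(t) mean(d[pt$type == t]), numeric(1)),
    median = vapply(1:4, function(t) stats::median(d[pt$type == t]), numeric(1)),
    n_pairs = vapply(1:4, function(t) sum(pt$type == t), integer(1))
  )
  attr(out, "excess_pct") <- 100 * (out$mean[2] / out$mean[1] - 1)
  attr(out, "excess_pct_median") <- 100 * (out$median[2] / out$median[1] - 1)
  class(out) <- c("pair_type_averages", class(out))
  out
}

#' Permutation test of convergence in pairwise distances
#'
#' Tests the null hypothesis that analogue pairs are no closer in shape
#' than non-analogue pairs by permuting the affiliation of non-focal
#' species across the focal-analogue pairs: the non-focal species labels
#' are randomly relabelled among themselves, preserving which focal species
#' has how many analogues, and the statistic (mean non-analogue distance
#' minus mean analogue distance) is recomputed. One-sided by default, in
#' the convergence direction.
#'
#' @param D Distance matrix (or `shape_gpa`, converted via
#'   [pairwise_procrustes_distances()]).
#' @param pairing An `analogue_pairing` with at least 2 analogue pairs.
#' @param n_perm Number of permutations.
#' @param seed Mandatory integer seed.
#' @param two_sided Use the absolute statistic instead.
#' @return A list with `p_value`, `statistic` (observed mean difference),
#'   `n_perm`, `seed`.
#' @export
convergence_permutation_test <- function(D, pairing, n_perm = 999, seed,
                                         two_sided = FALSE) {
  stopifnot(!missing(seed))
  if (inherits(D, "shape_gpa")) D <- pairwise_procrustes_distances(D)
  if (nrow(dplyr::as_tibble(pairing$pairs)) < 2) {
    stop("need at least 2 analogue pairs", call. = FALSE)
  }
  species <- rownames(D)
  focal <- intersect(species, pairing$focal_set)
  nonfocal <- setdiff(species, focal)
  A <- matrix(FALSE, length(focal), length(nonfocal),
              dimnames = list(focal, nonfocal))
  for (f in names(pairing$analogue_map)) {
    A[f, intersect(pairing$analogue_map[[f]], nonfocal)] <- TRUE
  }
  Dfn <- D[focal, nonfocal, drop = FALSE]
  stat <- function(M) mean(M[!A]) - mean(M[A])
  obs <- stat(Dfn)
  if (two_sided) obs <- abs(obs)
  hits <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      s <- stat(Dfn[, sample.int(ncol(Dfn)), drop = FALSE])
      if (two_sided) s <- abs(s)
      if (s >= obs) hits <- hits + 1L
    }
  })
  list(p_value = (hits + 1) / (n_perm + 1),
       statistic = if (two_sided) obs else mean(Dfn[!A]) - mean(Dfn[A]),
       n_perm = n_perm, seed = seed)
}

#' Wheatsheaf index of convergence strength
#'
#' The ratio of the average pairwise shape distance in a comparison set
#' (all pairs by default) to the average distance between designated
#' analogue pairs, oriented so values above 1 indicate convergence. In the
#' corrected form each pairwise distance is first divided by the pair's
#' expected Brownian-motion distance, `sqrt(C_ii + C_jj - 2 C_ij)`,
#' normalised to mean 1 across pairs, which penalises similarity that is
#' merely due to close phylogenetic relatedness.
#'
#' @param D Distance matrix with species dimnames.
#' @param pairing An `analogue_pairing`.
#' @param C Phylogenetic covariance matrix (required when `corrected`).
#' @param corrected Apply the phylogenetic penalty.
#' @param denominator `"all"` (default) or `"nonanalogue"`: the comparison
#'   set averaged in the numerator of the ratio.
#' @return The scalar index.
#' @export
wheatsheaf_index <- function(D, pairing, C = NULL, corrected = FALSE,
                             denominator = c("all", "nonanalogue")) {
  denominator <- match.arg(denominator)
  species <- rownames(D)
  pt <- pair_types(species, pairing)
  d <- D[cbind(pt$i, pt$j)]
  if (corrected) {
    if (is.null(C)) stop("corrected Wheatsheaf index needs C", call. = FALSE)
    C <- C[species, species]
    w <- sqrt(diag(C)[pt$i] + diag(C)[pt$j] - 2 * C[cbind(pt$i, pt$j)])
    w <- w / mean(w)
    if (any(w <= .Machine$double.eps)) {
      stop("zero expected divergence for some pair; cannot correct", call. = FALSE)
    }
    d <- d / w
  }
  m_analogue <- mean(d[pt$type == 1])
  if (m_analogue <= .Machine$double.eps) {
    stop("mean analogue distance is zero; index undefined", call. = FALSE)
  }
  m_comp <- if (denominator == "all") mean(d) else mean(d[pt$type == 2])
  m_comp / m_analogue
}

#' Remove a shape subspace from aligned coordinates
#'
#' Subtracts from the column-centred shape matrix its orthogonal projection
#' onto the span of `k` orthonormal shape loadings (e.g. the shape singular
#' vectors of the leading PLS dimensions). Distances computed from the
#' residual measure shape dissimilarity outside that subspace.
#'
#' @param alignment A `shape_gpa` or an `n x p` shape matrix.
#' @param x_loadings `p x k` matrix with orthonormal columns; `k = 0`
#'   (zero columns) leaves the data unchanged.
#' @param reorthonormalise Re-orthonormalise non-orthonormal loadings by QR
#'   instead of failing.
#' @return The `n x p` residual (column-centred) matrix.
#' @export
project_out_dimensions <- function(alignment, x_loadings,
                                   reorthonormalise = FALSE) {
  X <- if (inherits(alignment, "shape_gpa")) alignment$shapes else alignment
  Xc <- scale(X, scale = FALSE)
  U <- as.matrix(x_loadings)
  if (ncol(U) == 0) return(Xc)
  G <- crossprod(U)
  if (max(abs(G - diag(ncol(U)))) > 1e-8) {
    if (!reorthonormalise) stop("loadings are not orthonormal", call. = FALSE)
    U <- qr.Q(qr(U))
  }
  Xc - (Xc %*% U) %*% t(U)
}

#' Convergence report for one distance matrix
#'
#' Bundles [pair_type_averages()], [convergence_permutation_test()] and
#' (when a phylogenetic covariance is supplied) the [wheatsheaf_index()]
#' for a single set of pairwise distances.
#'
#' @param D Distance matrix with species dimnames (or `shape_gpa`).
#' @param pairing An `analogue_pairing`.
#' @param n_perm,seed Permutation settings.
#' @param C Optional phylogenetic covariance for the Wheatsheaf index.
#' @return An object of class `convergence_report`: list with `averages`,
#'   `excess_pct`, `p_value`, `wheatsheaf`, `wheatsheaf_uncorrected`,
#'   `n_perm`, `seed`.
#' @export
convergence_report <- function(D, pairing, n_perm = 999, seed, C = NULL) {
  if (inherits(D, "shape_gpa")) D <- pairwise_procrustes_distances(D)
  avg <- pair_type_averages(D, pairing)
  test <- convergence_permutation_test(D, pairing, n_perm = n_perm, seed = seed)
  ws_unc <- wheatsheaf_index(D, pairing, corrected = FALSE)
  ws <- if (!is.null(C)) wheatsheaf_index(D, pairing, C = C, corrected = TRUE)
        else NA_real_
  structure(
    list(averages = avg, excess_pct = attr(avg, "excess_pct"),
         p_value = test$p_value, statistic = test$statistic,
         wheatsheaf = ws, wheatsheaf_uncorrected = ws_unc,
         n_perm = n_perm, seed = seed),
    class = "convergence_report"
  )
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Convergence report\n")
  m <- x$averages$mean
  cat(sprintf("  mean distances: analogue %.4g | nonanalogue %.4g | within-focal %.4g | within-nonfocal %.4g\n",
              m[1], m[2], m[3], m[4]))
  cat(sprintf("  excess of nonanalogue over analogue pairs: %.1f%% (p = %.4g)\n",
              x$excess_pct, x$p_value))
  if (!is.na(x$wheatsheaf)) {
    cat(sprintf("  Wheatsheaf index: %.3f (uncorrected %.3f)\n",
                x$wheatsheaf, x$wheatsheaf_uncorrected))
  }
  invisible(x)
}

#' Convergence contrast inside and outside an adaptive shape subspace
#'
#' Splits the aligned shapes into the component inside the span of the
#' given orthonormal loadings (e.g. the leading PLS shape dimensions) and
#' the residual outside it, and produces a [convergence_report()] for each.
#' Squared within-subspace plus squared residual distances equal the full
#' squared distances (Pythagoras), so the contrast shows where the
#' convergence signal lives.
#'
#' @param alignment `shape_gpa` or `n x p` shape matrix.
#' @param x_loadings `p x k` orthonormal shape loadings.
#' @param pairing An `analogue_pairing`.
#' @param n_perm,seed Permutation settings.
#' @param C Optional phylogenetic covariance (for Wheatsheaf indices).
#' @return A list with elements `within` and `residual`, both
#'   `convergence_report`s.
#' @export
subspace_convergence_contrast <- function(alignment, x_loadings, pairing,
                                          n_perm = 999, seed, C = NULL) {
  X <- if (inherits(alignment, "shape_gpa")) alignment$shapes else alignment
  Xc <- scale(X, scale = FALSE)
  U <- as.matrix(x_loadings)
  resid <- project_out_dimensions(Xc, U)
  scores <- Xc %*% U
  rownames(scores) <- rownames(resid) <- rownames(X)
  D_within <- as.matrix(stats::dist(scores))
  D_resid <- as.matrix(stats::dist(resid))
  list(
    within = convergence_report(D_within, pairing, n_perm = n_perm,
                                seed = substream_seed(seed, 1), C = C),
    residual = convergence_report(D_resid, pairing, n_perm = n_perm,
                                  seed = substream_seed(seed, 2), C = C)
  )
}
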