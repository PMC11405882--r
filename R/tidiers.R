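#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Procrustes alignment
#'
#' @param x A `shape_gpa`.
#' @param ... Unused.
#' @return A long tibble of aligned coordinates: `specimen_id`, `index`,
#'   `x`, `y`, `z`, `centroid_size`, `reflected`.
#' @export
tidy.shape_gpa <- function(x, ...) {
  out <- array_to_landmarks(x$aligned)
  out$centroid_size <- x$centroid_sizes[out$specimen_id]
  out$reflected <- x$reflected[out$specimen_id]
  out[, c("specimen_id", "index", "x", "y", "z", "centroid_size", "reflected")]
}

#' @rdname tidy.shape_gpa
#' @export
glance.shape_gpa <- function(x, ...) {
  tibble::tibble(
    n_specimens = dim(x$aligned)[1], n_points = dim(x$aligned)[2],
    iterations = x$iterations, converged = x$converged,
    allow_reflection = x$allow_reflection, n_reflected = sum(x$reflected)
  )
}

#' Tidy a two-block PLS fit
#'
#' @param x A `shape_pls`.
#' @param matrix Which component to return: `"dimensions"` (default; one
#'   row per dimension with singular value, percentage of summed squared
#'   covariance, and p-value when available), `"scores"` (one row per
#'   species and dimension, paired shape and context scores), or
#'   `"y_loadings"` (context loadings).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.shape_pls <- function(x, matrix = c("dimensions", "scores", "y_loadings"),
                           ...) {
  matrix <- match.arg(matrix)
  k <- length(x$singular_values)
  if (matrix == "dimensions") {
    return(tibble::tibble(
      dimension = seq_len(k), singular_value = x$singular_values,
      pct_sq_cov = x$pct_sq_cov,
      p_value = if (is.null(x$p_values)) NA_real_
                else c(x$p_values, rep(NA_real_, k - length(x$p_values)))
    ))
  }
  if (matrix == "scores") {
    ids <- rownames(x$x_scores)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(x$x_scores)))
    return(tidyr::pivot_longer(
      dplyr::bind_cols(
        tibble::tibble(species_id = ids),
        stats::setNames(tibble::as_tibble(x$x_scores, .name_repair = "minimal"),
                        paste0("shape_dim", seq_len(k))),
        stats::setNames(tibble::as_tibble(x$y_scores, .name_repair = "minimal"),
                        paste0("context_dim", seq_len(k)))
      ),
      -"species_id",
      names_to = c("block", "dimension"), names_pattern = "(shape|context)_dim(\\d+)",
      names_transform = list(dimension = as.integer), values_to = "score"
    ))
  }
  tibble::tibble(
    variable = rep(rownames(x$y_loadings) %||% as.character(seq_len(nrow(x$y_loadings))),
                   k),
    dimension = rep(seq_len(k), each = nrow(x$y_loadings)),
    loading = as.vector(x$y_loadings)
  )
}

#' @rdname tidy.shape_pls
#' @export
glance.shape_pls <- function(x, ...) {
  tibble::tibble(
    n_dimensions = length(x$singular_values),
    pls1_pct_sq_cov = x$pct_sq_cov[1],
    pct_sq_cov_first4 = sum(x$pct_sq_cov[seq_len(min(4, length(x$pct_sq_cov)))]),
    phylogenetic = isTRUE(x$phylogenetic)
  )
}

#' Tidy a convergence report
#'
#' @param x A `convergence_report`.
#' @param ... Unused.
#' @return The pair-type averages tibble (`type`, `label`, `mean`,
#'   `median`, `n_pairs`).
#' @export
tidy.convergence_report <- function(x, ...) {
  out <- x$averages
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidy.convergence_report
#' @export
glance.convergence_report <- function(x, ...) {
  tibble::tibble(
    excess_pct = x$excess_pct, p_value = x$p_value,
    wheatsheaf = x$wheatsheaf,
    wheatsheaf_uncorrected = x$wheatsheaf_uncorrected,
    n_perm = x$n_perm
  )
}

#' Tidy a full convergence analysis
#'
#' @param x A `convergence_analysis`.
#' @param ... Unused.
#' @return One row per PLS dimension with test and signal statistics,
#'   joined with the overall convergence quantities repeated on row 1.
#' @export
tidy.convergence_analysis <- function(x, ...) {
  td <- tidy(x$pls)
  if (!is.null(x$blomberg_k)) {
    td <- dplyr::left_join(td, x$blomberg_k, by = "dimension")
  }
  td
}

#' @rdname tidy.convergence_analysis
#' @export
glance.convergence_analysis <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$convergence),
    tibble::tibble(
      pls1_pct_sq_cov = x$pls$pct_sq_cov[1],
      within_excess_pct = x$subspace$within$excess_pct %||% NA_real_,
      residual_excess_pct = x$subspace$residual$excess_pct %||% NA_real_,
      residual_p = x$subspace$residual$p_value %||% NA_real_
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
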