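#' Thin-plate-spline bending energy model
#'
#' Builds the bending-energy quadratic form of the 3D thin-plate spline
#' anchored on a reference configuration, using the kernel `U(r) = -r`
#' (conditionally positive definite in 3D). The energy of any target
#' configuration `Y` (or displacement field) is `tr(Y' B Y)` with `B` the
#' bending-energy matrix; affine maps of the reference have energy zero.
#'
#' @param reference A `k x 3` coordinate matrix without duplicate points.
#' @return An object of class `bending_energy` with fields `reference` and
#'   `energy_matrix` (`k x k`, symmetric positive semidefinite).
#' @export
bending_energy <- function(reference) {
  k <- nrow(reference)
  stopifnot(ncol(reference) == 3, k >= 5)
  r <- as.matrix(stats::dist(reference))
  if (min(r[upper.tri(r)]) <= .Machine$double.eps) {
    stop("kernel singularity: reference has duplicate points", call. = FALSE)
  }
  K <- -r
  Q <- cbind(1, reference)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 4, 4)))
  Linv <- solve(L)
  B <- Linv[seq_len(k), seq_len(k), drop = FALSE]
  B <- (B + t(B)) / 2
  structure(list(reference = reference, energy_matrix = B),
            class = "bending_energy")
}

#' Bending energy of a target configuration
#'
#' @param model A `bending_energy` model.
#' @param target A `k x 3` target configuration, or a `k x 3` displacement
#'   field added to the reference (the energy is identical: the quadratic
#'   form annihilates the affine part, including the reference itself).
#' @return Non-negative scalar energy.
#' @export
tps_energy <- function(model, target) {
  stopifnot(inherits(model, "bending_energy"),
            nrow(target) == nrow(model$reference))
  sum(diag(crossprod(target, model$energy_matrix %*% target)))
}

# unit tangent vectors for the sliding semilandmarks of one configuration,
# estimated by central differences along each curve path (forward/backward
# at open ends, wrapping on closed curves)
slider_tangents <- function(points, scheme) {
  k <- nrow(points)
  tangents <- matrix(NA_real_, k, 3)
  for (cv in scheme$curves) {
    path <- cv$path
    m <- length(path)
    for (j in seq_len(m)) {
      idx <- path[j]
      if (!(idx %in% cv$sliders)) next
      if (cv$closed) {
        nxt <- path[if (j == m) 1 else j + 1]
        prv <- path[if (j == 1) m else j - 1]
      } else {
        nxt <- path[min(j + 1, m)]
        prv <- path[max(j - 1, 1)]
      }
      tv <- points[nxt, ] - points[prv, ]
      nrm <- sqrt(sum(tv^2))
      if (nrm <= .Machine$double.eps) {
        stop(sprintf("tangent undefined at point %d (coincident curve neighbours)",
                     idx), call. = FALSE)
      }
      tangents[idx, ] <- tv / nrm
    }
  }
  tangents
}

#' Slide semilandmarks by damped bending-energy minimisation
#'
#' Moves each sliding semilandmark along its local curve tangent so as to
#' reduce the thin-plate-spline bending energy of the deformation from the
#' reference to the configuration. At each iteration the unconstrained
#' energy-minimising step along the current tangents is computed and only a
#' fraction `damping` of it is applied (the default 0.1 keeps sliding stable
#' when curve shape varies strongly across the sample, at the cost of more
#' iterations); tangents are re-estimated after every step. Anatomical
#' landmarks and curve anchors never move. Descent is monotone: each damped
#' step reduces (never increases) the bending energy.
#'
#' @param configs `n x k x 3` array (or single `k x 3` matrix, or long
#'   landmark tibble) of configurations to slide.
#' @param scheme A `landmark_scheme` providing the sliding topology.
#' @param reference `k x 3` reference configuration (typically the GPA
#'   consensus).
#' @param damping Fraction of the minimising step applied per iteration,
#'   in (0, 1].
#' @param tol Convergence tolerance on the RMS tangential step.
#' @param max_iter Maximum sliding iterations per configuration.
#' @return An array (or matrix) of slid configurations with the same shape
#'   as the input, with attribute `"iterations"` (per-configuration counts).
#' @export
slide_semilandmarks <- function(configs, scheme, reference, damping = 0.1,
                                tol = 1e-6, max_iter = 200) {
  single <- is.matrix(configs)
  arr <- if (single) array(configs, c(1, nrow(configs), 3))
         else if (is.array(configs) && length(dim(configs)) == 3) configs
         else landmarks_to_array(configs, scheme)
  stopifnot(damping > 0, damping <= 1, dim(arr)[2] == scheme$n_points,
            nrow(reference) == scheme$n_points)
  model <- bending_energy(reference)
  B <- model$energy_matrix
  sliders <- sort(unlist(lapply(scheme$curves, `[[`, "sliders")))
  iters <- integer(dim(arr)[1])
  scale_ref <- sqrt(sum(sweep(reference, 2, colMeans(reference))^2))
  for (i in seq_len(dim(arr)[1])) {
    Y <- arr[i, , ]
    for (it in seq_len(max_iter)) {
      U <- slider_tangents(Y, scheme)[sliders, , drop = FALSE]
      G <- B %*% Y                       # k x 3 energy gradient / 2
      g <- 2 * rowSums(U * G[sliders, , drop = FALSE])
      H <- 2 * B[sliders, sliders] * tcrossprod(U)
      ridge <- 1e-12 * max(abs(diag(H)), 1e-300)
      t_full <- solve(H + diag(ridge, length(sliders)), -g)
      step <- damping * t_full
      Y[sliders, ] <- Y[sliders, ] + step * U
      iters[i] <- it
      if (sqrt(mean(step^2)) < tol * scale_ref) break
    }
    arr[i, , ] <- Y
  }
  out <- if (single) arr[1, , ] else arr
  attr(out, "iterations") <- iters
  out
}

#' Joint semilandmark sliding and Procrustes alignment
#'
#' Alternates [gpa()] and [slide_semilandmarks()] against the evolving
#' consensus until the consensus stabilises. This is the standard treatment
#' of curve semilandmarks: sliding is defined relative to the sample mean
#' shape, which itself changes as points slide.
#'
#' @param data Long landmark tibble or `n x k x 3` array.
#' @param scheme A `landmark_scheme`.
#' @param allow_reflection Passed to [gpa()].
#' @param damping,slide_tol,slide_max_iter Passed to [slide_semilandmarks()].
#' @param outer_tol RMS consensus change below which the alternation stops.
#' @param max_outer Maximum number of slide/GPA alternations.
#' @return A list with `alignment` (final `shape_gpa` of the slid
#'   configurations), `slid` (the slid, aligned unit-size coordinates as an
#'   array), and `outer_iterations`.
#' @export
slide_and_align <- function(data, scheme = labyrinth_scheme(),
                            allow_reflection = TRUE, damping = 0.1,
                            slide_tol = 1e-6, slide_max_iter = 50,
                            outer_tol = 1e-6, max_outer = 10) {
  arr <- if (is.array(data) && length(dim(data)) == 3) data
         else landmarks_to_array(data, scheme)
  fit <- gpa(arr, allow_reflection = allow_reflection)
  outer <- 0
  repeat {
    outer <- outer + 1
    consensus <- fit$consensus
    slid <- slide_semilandmarks(fit$aligned, scheme, consensus,
                                damping = damping, tol = slide_tol,
                                max_iter = slide_max_iter)
    fit <- gpa(slid, allow_reflection = allow_reflection)
    delta <- sqrt(mean((fit$consensus - consensus)^2))
    if (delta < outer_tol || outer >= max_outer) break
  }
  list(alignment = fit, slid = fit$aligned, outer_iterations = outer)
}
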