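#' Configuration of a full convergence analysis
#'
#' Collects the inputs and tuning parameters of [run_full_analysis()].
#' Inputs may be in-memory objects (long landmark tibble, context tibble,
#' `ape::phylo`, `analogue_pairing`) or file paths understood by the
#' package readers.
#'
#' @param landmarks Long landmark tibble or path to a long-CSV file.
#' @param context Context tibble or CSV path.
#' @param pairing `analogue_pairing` or CSV path.
#' @param tree Optional `ape::phylo` or Newick path (enables the
#'   phylogenetic stages).
#' @param seed Mandatory integer master seed; every stochastic stage uses a
#'   substream derived from it.
#' @param slide Run bending-energy semilandmark sliding before GPA-based
#'   analyses.
#' @param damping Sliding damping factor (fraction of the minimising step
#'   applied per iteration).
#' @param allow_reflection Allow mirroring in the superimposition.
#' @param n_perm Permutations for all permutation tests.
#' @param n_dims_adaptive Number of leading PLS dimensions treated as the
#'   adaptive subspace (tested, K-scored, and removed in the contrast).
#' @param log_body_mass Log-transform body mass before standardisation.
#' @param wheatsheaf_denominator `"all"` or `"nonanalogue"`.
#' @param stability One of `"none"`, `"loo"`, `"l2o"`, `"leave_pair_out"`.
#' @param scheme Landmark scheme.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(landmarks, context, pairing, tree = NULL, seed,
                            slide = TRUE, damping = 0.1,
                            allow_reflection = TRUE, n_perm = 999,
                            n_dims_adaptive = 4, log_body_mass = TRUE,
                            wheatsheaf_denominator = "all",
                            stability = c("none", "loo", "l2o", "leave_pair_out"),
                            scheme = labyrinth_scheme()) {
  stopifnot(!missing(seed), n_dims_adaptive >= 0)
  structure(
    list(landmarks = landmarks, context = context, pairing = pairing,
         tree = tree, seed = as.integer(seed), slide = slide,
         damping = damping, allow_reflection = allow_reflection,
         n_perm = n_perm, n_dims_adaptive = as.integer(n_dims_adaptive),
         log_body_mass = log_body_mass,
         wheatsheaf_denominator = wheatsheaf_denominator,
         stability = match.arg(stability), scheme = scheme),
    class = "analysis_config"
  )
}

resolve_inputs <- function(config) {
  lm <- config$landmarks
  if (is.character(lm)) lm <- read_landmarks(lm, config$scheme)
  ctx <- config$context
  if (is.character(ctx)) ctx <- read_context_table(ctx)
  else ctx <- validate_context_table(ctx)
  pr <- config$pairing
  if (is.character(pr)) pr <- read_pairing(pr)
  tr <- config$tree
  if (is.character(tr)) tr <- read_newick(tr)
  list(landmarks = lm, context = ctx, pairing = pr, tree = tr)
}

#' Run the full convergence analysis
#'
#' Executes the complete pipeline: (optional) semilandmark sliding and
#' Procrustes alignment, pairwise Procrustes distances, the four pair-type
#' averages with the affiliation permutation test and Wheatsheaf index,
#' two-block PLS of shape against the standardised contextual variables
#' with hierarchical permutation tests, phylogenetic PLS, Blomberg's K of
#' the PLS shape and context scores, and the convergence contrast inside
#' versus outside the adaptive PLS subspace. All stages are seeded from the
#' master seed; rerunning with the same configuration reproduces the report
#' exactly.
#'
#' @param config An [analysis_config()], or a `synthetic_study` (its
#'   components are used and remaining arguments are taken from `...`).
#' @param ... When `config` is a `synthetic_study`: overrides passed to
#'   [analysis_config()] (e.g. `n_perm`, `slide`).
#' @return An object of class `convergence_analysis`: list with elements
#'   `alignment`, `distances`, `convergence` (a `convergence_report`),
#'   `pls`, `phylo_pls`, `blomberg_k` (tibble), `subspace` (within/residual
#'   reports) and `config`.
#' @export
run_full_analysis <- function(config, ...) {
  if (inherits(config, "synthetic_study")) {
    study <- config
    config <- analysis_config(landmarks = study$landmarks,
                              context = study$context,
                              pairing = study$pairing, tree = study$tree,
                              seed = study$config$seed, ...)
  }
  stopifnot(inherits(config, "analysis_config"))
  inp <- resolve_inputs(config)
  seed <- config$seed

  fit <- if (config$slide) {
    slide_and_align(inp$landmarks, config$scheme,
                    allow_reflection = config$allow_reflection,
                    damping = config$damping)$alignment
  } else {
    gpa(inp$landmarks, allow_reflection = config$allow_reflection,
        scheme = config$scheme)
  }
  species <- rownames(fit$shapes)
  D <- pairwise_procrustes_distances(fit)
  C <- if (!is.null(inp$tree)) phylo_covariance(inp$tree, species) else NULL

  conv <- convergence_report(D, inp$pairing, n_perm = config$n_perm,
                             seed = substream_seed(seed, 11), C = C)

  ctx <- inp$context[match(species, inp$context$species_id), ]
  Y <- standardize_context(ctx, log_body_mass = config$log_body_mass)
  pls <- two_block_pls(fit$shapes, Y)
  n_test <- min(config$n_dims_adaptive, length(pls$singular_values))
  if (n_test > 0) {
    pls$p_values <- hierarchical_permutation_test(
      fit$shapes, Y, n_dims = n_test, n_perm = config$n_perm,
      seed = substream_seed(seed, 12))
  }

  phylo_pls <- if (!is.null(C))
    phylogenetic_two_block_pls(fit$shapes, Y, C) else NULL

  ktab <- NULL
  if (!is.null(C) && n_test > 0) {
    ktab <- tibble::tibble(
      dimension = seq_len(n_test),
      k_shape = vapply(seq_len(n_test), function(j)
        blomberg_k(stats::setNames(pls$x_scores[, j], species), C), numeric(1)),
      k_context = vapply(seq_len(n_test), function(j)
        blomberg_k(stats::setNames(pls$y_scores[, j], species), C), numeric(1))
    )
  }

  subspace <- NULL
  if (config$n_dims_adaptive > 0) {
    U <- pls$x_loadings[, seq_len(n_test), drop = FALSE]
    subspace <- subspace_convergence_contrast(
      fit, U, inp$pairing, n_perm = config$n_perm,
      seed = substream_seed(seed, 13), C = C)
  } else {
    subspace <- list(within = NULL, residual = conv)
  }

  structure(
    list(alignment = fit, distances = D, convergence = conv, pls = pls,
         phylo_pls = phylo_pls, blomberg_k = ktab, subspace = subspace,
         config = config),
    class = "convergence_analysis"
  )
}

#' @export
print.convergence_analysis <- function(x, ...) {
  cat("== Convergence analysis ==\n")
  print(x$alignment)
  print(x$convergence)
  print(x$pls)
  if (!is.null(x$blomberg_k)) {
    cat("  Blomberg's K (shape scores):",
        sprintf("%.2f", x$blomberg_k$k_shape), "\n")
  }
  if (!is.null(x$subspace$within)) {
    cat(sprintf("  subspace contrast: within excess %.1f%%, residual excess %.1f%% (p = %.3g)\n",
                x$subspace$within$excess_pct, x$subspace$residual$excess_pct,
                x$subspace$residual$p_value))
  }
  invisible(x)
}

#' Serialise a convergence analysis to a JSON report
#'
#' @param analysis A `convergence_analysis`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_analysis_report <- function(analysis, path) {
  cfg <- analysis$config
  results <- list(
    pair_type_averages = as.data.frame(analysis$convergence$averages),
    excess_pct = analysis$convergence$excess_pct,
    convergence_p = analysis$convergence$p_value,
    wheatsheaf = analysis$convergence$wheatsheaf,
    wheatsheaf_uncorrected = analysis$convergence$wheatsheaf_uncorrected,
    pls = list(singular_values = analysis$pls$singular_values,
               pct_sq_cov = analysis$pls$pct_sq_cov,
               p_values = analysis$pls$p_values),
    blomberg_k = if (!is.null(analysis$blomberg_k))
      as.data.frame(analysis$blomberg_k),
    subspace = if (!is.null(analysis$subspace$within)) list(
      within_excess_pct = analysis$subspace$within$excess_pct,
      within_p = analysis$subspace$within$p_value,
      residual_excess_pct = analysis$subspace$residual$excess_pct,
      residual_p = analysis$subspace$residual$p_value)
  )
  write_report_json(results, path, report_type = "convergence_analysis",
                    parameters = list(seed = cfg$seed, n_perm = cfg$n_perm,
                                      slide = cfg$slide, damping = cfg$damping,
                                      n_dims_adaptive = cfg$n_dims_adaptive,
                                      allow_reflection = cfg$allow_reflection))
}

#' Leave-k-out stability analysis
#'
#' Repeats the distance comparison and the PLS for all samples with one
#' species (`"loo"`), two species (`"l2o"`), or one whole analogue pair
#' group (`"leave_pair_out"`: a focal species together with its analogue
#' set) removed. Superimposition is rerun per replicate, since the
#' consensus changes with sample composition; when sliding is enabled it is
#' performed once on the full sample and the slid coordinates are re-aligned
#' per replicate. Replicates whose reduced pairing no longer supports the
#' contrast (an empty pair class or fewer than 2 analogue pairs) are
#' flagged and skipped.
#'
#' @param config An [analysis_config()] (or `synthetic_study`, see
#'   [run_full_analysis()]).
#' @param mode Overrides `config$stability`.
#' @param ... Passed through when `config` is a `synthetic_study`.
#' @return A `stability_report` tibble with one row per replicate:
#'   `left_out`, the four pair-type means, `excess_pct`, `pls1_pct_sq_cov`,
#'   `pls1_loading_cor` (absolute vector correlation with the full-sample
#'   first shape loading), `skipped`. Dispersion summaries are in
#'   `attr(, "summary")`.
#' @export
leave_k_out <- function(config, mode = NULL, ...) {
  if (inherits(config, "synthetic_study")) {
    study <- config
    config <- analysis_config(landmarks = study$landmarks,
                              context = study$context,
                              pairing = study$pairing, tree = study$tree,
                              seed = study$config$seed, ...)
  }
  if (is.null(mode)) mode <- config$stability
  stopifnot(mode %in% c("loo", "l2o", "leave_pair_out"))
  inp <- resolve_inputs(config)
  arr <- landmarks_to_array(inp$landmarks, config$scheme)
  if (config$slide) {
    arr <- slide_and_align(arr, config$scheme,
                           allow_reflection = config$allow_reflection,
                           damping = config$damping)$slid
  }
  species <- dimnames(arr)[[1]]
  n <- length(species)

  sets <- switch(mode,
    loo = as.list(species),
    l2o = utils::combn(species, 2, simplify = FALSE),
    leave_pair_out = lapply(names(inp$pairing$analogue_map), function(f)
      c(f, inp$pairing$analogue_map[[f]]))
  )

  # full-sample reference PLS loading for sign-aligned comparison
  full_fit <- gpa(arr, allow_reflection = config$allow_reflection)
  ctx_all <- inp$context[match(species, inp$context$species_id), ]
  Y_all <- standardize_context(ctx_all, log_body_mass = config$log_body_mass)
  full_pls <- two_block_pls(full_fit$shapes, Y_all)
  ref_loading <- full_pls$x_loadings[, 1]

  rows <- purrr::map_dfr(seq_along(sets), function(i) {
    keep <- setdiff(species, sets[[i]])
    out <- tibble::tibble(
      replicate = i, left_out = paste(sets[[i]], collapse = "+"),
      mean_analogue = NA_real_, mean_nonanalogue = NA_real_,
      mean_within_focal = NA_real_, mean_within_nonfocal = NA_real_,
      excess_pct = NA_real_, pls1_pct_sq_cov = NA_real_,
      pls1_loading_cor = NA_real_, skipped = TRUE)
    sub_pairs <- inp$pairing$pairs[inp$pairing$pairs$focal %in% keep &
                                     inp$pairing$pairs$analogue %in% keep, ]
    if (nrow(sub_pairs) < 2) return(out)
    sub_pairing <- as_analogue_pairing(dplyr::bind_rows(
      sub_pairs,
      tibble::tibble(focal = setdiff(intersect(inp$pairing$focal_set, keep),
                                     sub_pairs$focal),
                     analogue = NA_character_)))
    fit <- gpa(arr[keep, , , drop = FALSE],
               allow_reflection = config$allow_reflection)
    D <- pairwise_procrustes_distances(fit)
    avg <- tryCatch(pair_type_averages(D, sub_pairing), error = function(e) NULL)
    if (is.null(avg)) return(out)
    ctx <- inp$context[match(keep, inp$context$species_id), ]
    Y <- tryCatch(standardize_context(ctx, log_body_mass = config$log_body_mass),
                  error = function(e) NULL)
    if (is.null(Y)) return(out)
    pls <- two_block_pls(fit$shapes, Y, n_dims = 1)
    out$mean_analogue <- avg$mean[1]; out$mean_nonanalogue <- avg$mean[2]
    out$mean_within_focal <- avg$mean[3]; out$mean_within_nonfocal <- avg$mean[4]
    out$excess_pct <- attr(avg, "excess_pct")
    out$pls1_pct_sq_cov <- pls$pct_sq_cov[1]
    # rotate the replicate loading into the full-sample frame before comparing
    os <- optimal_superposition(fit$consensus, full_fit$consensus,
                                allow_reflection = config$allow_reflection)
    loading_rot <- as.vector(t(matrix(pls$x_loadings[, 1],
                                      ncol(fit$shapes) / 3, 3,
                                      byrow = TRUE) %*% os$rotation))
    out$pls1_loading_cor <- abs(stats::cor(loading_rot, ref_loading))
    out$skipped <- FALSE
    out
  })
  attr(rows, "summary") <- dplyr::summarise(
    dplyr::filter(rows, !.data$skipped),
    n_replicates = dplyr::n(),
    excess_pct_min = min(.data$excess_pct),
    excess_pct_median = stats::median(.data$excess_pct),
    excess_pct_max = max(.data$excess_pct),
    pls1_cor_min = min(.data$pls1_loading_cor),
    pls1_cor_median = stats::median(.data$pls1_loading_cor))
  attr(rows, "mode") <- mode
  class(rows) <- c("stability_report", class(rows))
  rows
}
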