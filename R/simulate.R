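# parametric template geometry ------------------------------------------

circle_points <- function(center, radius, e1, e2, theta) {
  t(vapply(theta, function(th)
    center + radius * (cos(th) * e1 + sin(th) * e2), numeric(3)))
}

unitv <- function(v) v / sqrt(sum(v^2))

# k x 3 matrix of template coordinates in scheme order (13 LM then 111 SL)
template_points <- function(cochlea_turns = 2.5) {
  sch <- labyrinth_scheme()
  P <- matrix(NA_real_, sch$n_points, 3)

  # anterior semicircular canal: vertical plane oblique to the midline
  eA1 <- c(0, 0, 1); eA2 <- unitv(c(-1, -1, 0))
  cA <- c(0.5, 0.6, 1.3)
  thA <- seq(0, 5.3, length.out = 23)          # LM1, 2 SL, LM2, 18 SL, LM3
  asc <- circle_points(cA, 1.0, eA1, eA2, thA)
  # posterior canal: mirrored obliquity, translated so its end meets the
  # ASC end (the common crus junction, LM 3)
  eP1 <- c(0, 0, 1); eP2 <- unitv(c(-1, 1, 0))
  cP <- c(0.5, -0.6, 1.3)
  thP <- seq(0, 5.3, length.out = 23)
  psc <- circle_points(cP, 0.95, eP1, eP2, thP)
  psc <- sweep(psc, 2, psc[23, ] - asc[23, ])  # force shared junction
  # lateral canal: horizontal plane
  lsc <- circle_points(c(1.2, 0.1, 0.35), 0.8, c(1, 0, 0), c(0, 1, 0),
                       seq(0, 5.0, length.out = 23))

  lm3 <- asc[23, ]
  lm4 <- lm3 + c(0.12, 0.05, -1.1)
  # common crus: LM3 -> LM4 with a slight lateral bow
  s <- seq(0, 1, length.out = 7)
  cc <- t(vapply(s, function(u) (1 - u) * lm3 + u * lm4 +
                   sin(pi * u) * c(0.08, 0, 0), numeric(3)))

  # conical cochlear spiral, 40 SL from base to the apex (LM 10)
  n_coch <- 41
  u <- seq(0, 1, length.out = n_coch)
  th <- 2 * pi * cochlea_turns * u
  r <- 0.75 * (1 - 0.92 * u)
  base <- c(0.9, 1.3, -0.35)
  coch <- cbind(base[1] + r * cos(th), base[2] + r * sin(th),
                base[3] - 0.7 * u)

  # oval window ellipse (closed curve through LM 13 and LM 12)
  ow_c <- c(1.05, 0.45, 0.3)
  ow_e1 <- c(0, 1, 0); ow_e2 <- unitv(c(-0.3, 0, 1))
  ow_th <- 2 * pi * (0:7) / 8
  ow <- t(vapply(ow_th, function(t_)
    ow_c + 0.33 * cos(t_) * ow_e1 + 0.18 * sin(t_) * ow_e2, numeric(3)))

  # anatomical landmarks
  P[1, ] <- asc[1, ];  P[2, ] <- asc[4, ];  P[3, ] <- lm3; P[4, ] <- lm4
  P[5, ] <- psc[4, ];  P[6, ] <- psc[1, ]
  P[7, ] <- lsc[23, ]; P[8, ] <- lsc[4, ]; P[9, ] <- lsc[1, ]
  P[10, ] <- coch[n_coch, ]
  P[11, ] <- coch[1, ] + c(0.15, -0.2, 0.1)   # round window centre
  P[13, ] <- ow[1, ];  P[12, ] <- ow[5, ]
  # semilandmarks, scheme order
  P[13 + (1:2), ] <- asc[2:3, ];   P[13 + (3:20), ] <- asc[5:22, ]
  P[13 + (21:22), ] <- psc[2:3, ]; P[13 + (23:40), ] <- psc[5:22, ]
  P[13 + (41:45), ] <- cc[2:6, ]
  P[13 + (46:47), ] <- lsc[2:3, ]; P[13 + (48:65), ] <- lsc[5:22, ]
  P[13 + (66:105), ] <- coch[1:40, ]
  P[13 + (106:108), ] <- ow[2:4, ]; P[13 + (109:111), ] <- ow[6:8, ]
  P
}

#' Template labyrinth-like landmark configuration
#'
#' A smooth parametric stand-in for a mammalian bony labyrinth matching the
#' default landmark scheme: three mutually oblique near-circular canal
#' curves (20 semilandmarks each) joined at a common crus (5), a conical
#' cochlear spiral (40, with a configurable number of turns), a closed oval
#' window outline (6), and 13 anatomical anchor landmarks. It is synthetic
#' geometry for simulation and testing, not a measured specimen.
#'
#' @param cochlea_turns Number of spiral turns of the cochlear curve.
#' @return A long landmark tibble for a single specimen `"template"`.
#' @examples
#' tpl <- make_template_labyrinth()
#' nrow(tpl)  # 124 points
#' @export
make_template_labyrinth <- function(cochlea_turns = 2.5) {
  P <- template_points(cochlea_turns)
  arr <- array(P, c(1, nrow(P), 3), dimnames = list("template", NULL, NULL))
  array_to_landmarks(arr, labyrinth_scheme())
}

# study configuration -----------------------------------------------------

#' Configuration for a synthetic convergence study
#'
#' Defines the conditions under which [simulate_study()] generates data.
#' Magnitudes are expressed as fractions of the template centroid size so
#' they are meaningful regardless of the template's units: the per-tip
#' Brownian-motion shape dispersion (`bm_frac`, expected total deviation
#' norm at the tips), the convergent displacement per ecological regime
#' (`effect_frac`, the planted signal), and the digitising noise
#' (`noise_frac`). Defaults plant a strong but incomplete convergence
#' signal: the leading regime displaces shapes by four times the Brownian
#' dispersion, the second by about half that.
#'
#' @param seed Integer seed (mandatory; every stochastic step derives a
#'   substream from it).
#' @param n_species,n_focal Total species and size of the focal clade.
#' @param tree_model `"pure_birth"` (two pure-birth clades joined at a
#'   basal split of unit depth) or `"fixed_newick"`.
#' @param newick Newick string used when `tree_model = "fixed_newick"`.
#' @param bm_frac,noise_frac Magnitudes as fractions of the template
#'   centroid size (see Details).
#' @param effect_frac Convergent displacement per regime as a fraction of
#'   the template centroid size; scalar or vector of length `n_regimes`.
#'   The default gives regimes geometrically decreasing strengths
#'   (`0.08 * 0.6^(r-1)`) so that successive PLS dimensions are well
#'   separated, as in real adaptive data where one ecological contrast
#'   dominates.
#' @param n_regimes Number of planted convergent regimes.
#' @param n_analogues_per_regime Non-focal species recruited per regime.
#' @param context_noise Ordinal misclassification rate in the context table.
#' @param cochlea_turns Template parameter.
#' @param planted_loadings Optional `372 x n_regimes` orthonormal matrix of
#'   planted shape directions (default: seeded random orthonormal basis).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed, n_species = 40, n_focal = 20,
                              tree_model = c("pure_birth", "fixed_newick"),
                              newick = NULL,
                              bm_frac = 0.02, effect_frac = NULL,
                              noise_frac = 0.004, n_regimes = 2,
                              n_analogues_per_regime = 3,
                              context_noise = 0.1, cochlea_turns = 2.5,
                              planted_loadings = NULL) {
  if (is.null(effect_frac)) effect_frac <- 0.08 * 0.6^(seq_len(n_regimes) - 1)
  effect_frac <- rep_len(effect_frac, n_regimes)
  stopifnot(!missing(seed), n_focal < n_species, n_species >= 6,
            n_regimes >= 1, bm_frac >= 0, all(effect_frac >= 0),
            noise_frac >= 0)
  structure(
    list(seed = as.integer(seed), n_species = as.integer(n_species),
         n_focal = as.integer(n_focal), tree_model = match.arg(tree_model),
         newick = newick, bm_frac = bm_frac, effect_frac = effect_frac,
         noise_frac = noise_frac, n_regimes = as.integer(n_regimes),
         n_analogues_per_regime = as.integer(n_analogues_per_regime),
         context_noise = context_noise, cochlea_turns = cochlea_turns,
         planted_loadings = planted_loadings),
    class = "simulation_config"
  )
}

# newick fragment for a clade of given labels with internal depth `depth`
clade_newick <- function(n, labels, depth, stem) {
  if (n == 1) return(sprintf("%s:%g", labels, stem + depth))
  t <- ape::rphylo(n, birth = 1, death = 0)
  t$tip.label <- labels
  t$edge.length <- t$edge.length * depth /
    max(ape::node.depth.edgelength(t)[seq_len(n)])
  sprintf("%s:%g", sub(";$", "", ape::write.tree(t)), stem)
}

#' Simulate an ultrametric study tree
#'
#' Under the default `"pure_birth"` model, the tree is a basal split of
#' unit depth joining two pure-birth clades: the focal clade (`n_focal`
#' tips, labels `F..`, stem length 0.4 so the clade is phylogenetically
#' coherent) and the pool of potential analogues (`N..` tips, stem length
#' 0.05 so they diverge close to the root, like analogues drawn from
#' across a whole class).
#'
#' @param config A `simulation_config`.
#' @return An ultrametric [ape::phylo] tree of depth 1.
#' @export
simulate_tree <- function(config) {
  if (config$tree_model == "fixed_newick") {
    return(ape::read.tree(text = config$newick))
  }
  nf <- config$n_focal; nn <- config$n_species - nf
  with_seed(substream_seed(config$seed, 101), {
    s1 <- clade_newick(nf, sprintf("F%02d", seq_len(nf)), depth = 0.6, stem = 0.4)
    s2 <- clade_newick(nn, sprintf("N%02d", seq_len(nn)), depth = 0.95, stem = 0.05)
    ape::read.tree(text = sprintf("(%s,%s);", s1, s2))
  })
}

# threshold a latent score into an ordinal range
to_ordinal <- function(latent, min_level, max_level) {
  pmin(pmax(round(min_level + latent), min_level), max_level)
}

#' Simulate a complete synthetic convergence study
#'
#' Generates landmark configurations, an ultrametric tree, a context table
#' and an analogue pairing with known ground truth. Species shapes are the
#' template plus Brownian-motion deviations accumulated along the tree,
#' plus a convergent displacement `effect * regime_score * loading_r` for
#' each planted regime, plus digitising noise; each specimen is then given
#' a random rigid motion, scale, and (for left-sided specimens) a
#' reflection, all of which downstream superimposition must remove.
#' Regimes are assigned to contiguous blocks of the focal clade and to
#' randomly scattered non-focal species (the cross-clade analogue sets);
#' the pairing maps each focal regime member to the non-focal members of
#' its regime, and focal species without a regime are unpaired. Ordinal
#' context variables designated to a regime are generated from the regime
#' score plus Gaussian noise, thresholded to their level ranges, with
#' additional misclassification at rate `context_noise`; the remaining
#' variables (and log body mass) evolve by Brownian motion on the tree.
#'
#' @param config A [simulation_config()].
#' @return An object of class `synthetic_study`: list with `landmarks`
#'   (long tibble), `tree`, `context`, `pairing`, `config` and `truth`
#'   (regime scores, planted loadings and effect sizes, template).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sch <- labyrinth_scheme()
  tpl <- template_points(config$cochlea_turns)
  k <- nrow(tpl); p <- 3 * k
  cs <- centroid_size(tpl)
  tree <- simulate_tree(config)
  species <- tree$tip.label
  n <- length(species)
  focal <- grep("^F", species, value = TRUE)
  nonfocal <- setdiff(species, focal)
  C <- phylo_covariance(tree, species)

  # planted orthonormal loadings in the template coordinate frame
  U <- config$planted_loadings
  if (is.null(U)) {
    U <- with_seed(substream_seed(config$seed, 202), {
      qr.Q(qr(matrix(stats::rnorm(p * config$n_regimes), p, config$n_regimes)))
    })
  }
  if (max(abs(crossprod(U) - diag(ncol(U)))) > 1e-8) {
    stop("planted loadings are not orthonormal", call. = FALSE)
  }

  # regime membership: contiguous blocks of the focal clade (tree order),
  # scattered analogue sets among the non-focal species
  nr <- config$n_regimes
  block <- max(1L, min(floor(length(focal) / (nr + 1)), 6L))
  if (nr * block > length(focal)) block <- max(1L, floor(length(focal) / nr))
  regime <- matrix(0, n, nr, dimnames = list(species, NULL))
  regime <- with_seed(substream_seed(config$seed, 303), {
    focal_order <- intersect(tree$tip.label, focal)
    pool <- nonfocal
    for (r in seq_len(nr)) {
      members_f <- focal_order[seq((r - 1) * block + 1, r * block)]
      n_take <- min(config$n_analogues_per_regime, length(pool) - (nr - r))
      if (n_take < 1) stop("too few non-focal species for the regime design",
                           call. = FALSE)
      members_n <- sample(pool, n_take)
      pool <- setdiff(pool, members_n)
      regime[members_f, r] <- 1
      regime[members_n, r] <- 1
    }
    regime
  })

  # shapes: template + BM + planted convergent displacement + noise
  bm_sd <- config$bm_frac * cs / sqrt(p)
  eff <- config$effect_frac * cs                      # one magnitude per regime
  noise_sd <- config$noise_frac * cs / sqrt(p)
  shapes <- with_seed(substream_seed(config$seed, 404), {
    dev <- sim_bm_traits(C, n_traits = p, sigma2 = bm_sd^2)[species, , drop = FALSE]
    dev <- dev + (regime %*% diag(eff, nrow = nr)) %*% t(U)
    dev + matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
  })
  flat_tpl <- as.vector(t(tpl))                                  # x,y,z per point
  raw <- sweep(shapes, 2, -flat_tpl)                             # add template

  # random similarity motions + side/reflection per specimen
  arr <- array(NA_real_, c(n, k, 3), dimnames = list(species, NULL, c("x", "y", "z")))
  sides <- with_seed(substream_seed(config$seed, 505), {
    side <- sample(c("left", "right"), n, replace = TRUE)
    for (i in seq_len(n)) {
      M <- matrix(raw[i, ], k, 3, byrow = TRUE)
      if (side[i] == "left") M[, 1] <- -M[, 1]
      Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
      if (det(Q) < 0) Q[, 1] <- -Q[, 1]
      M <- M %*% Q * stats::runif(1, 0.8, 1.25)
      M <- sweep(M, 2, stats::runif(3, -5, 5), `+`)
      arr[i, , ] <- M
    }
    side
  })

  landmarks <- array_to_landmarks(arr, sch, species_id = species, side = sides)

  # context table
  meta <- context_variables()
  regime_vars <- c("aquatic", "fossorial", "arboreal", "cursorial",
                   "leaping", "scansorial")[seq_len(nr)]
  context <- with_seed(substream_seed(config$seed, 606), {
    ctx <- tibble::tibble(species_id = species)
    lat_bm <- sim_bm_traits(C, n_traits = nrow(meta), sigma2 = 1)
    for (j in seq_len(nrow(meta))) {
      v <- meta$variable[j]
      if (v == "body_mass") {
        ctx[[v]] <- exp(log(500) + 1.5 * lat_bm[species, j])
      } else if (v %in% regime_vars) {
        r <- match(v, regime_vars)
        lat <- 2.5 * regime[species, r] + stats::rnorm(n, sd = 0.5)
        lev <- to_ordinal(lat, meta$min_level[j], meta$max_level[j])
        flip <- stats::runif(n) < config$context_noise
        lev[flip] <- to_ordinal(lev[flip] - meta$min_level[j] +
                                  sample(c(-1, 1), sum(flip), replace = TRUE),
                                meta$min_level[j], meta$max_level[j])
        ctx[[v]] <- lev
      } else {
        # half heritable (BM on the tree), half independent behavioural noise
        span <- meta$max_level[j] - meta$min_level[j]
        z <- (lat_bm[species, j] / sqrt(mean(diag(C))) + stats::rnorm(n)) / sqrt(2)
        ctx[[v]] <- to_ordinal(span * stats::pnorm(z),
                               meta$min_level[j], meta$max_level[j])
      }
    }
    # guard against degenerate zero-variance columns in small samples
    for (v in setdiff(meta$variable, "body_mass")) {
      if (stats::var(ctx[[v]]) == 0) {
        i <- sample.int(n, 1)
        j <- match(v, meta$variable)
        ctx[[v]][i] <- if (ctx[[v]][i] < meta$max_level[j]) ctx[[v]][i] + 1
                       else ctx[[v]][i] - 1
      }
    }
    ctx$habitat_label <- dplyr::case_when(
      regime[species, 1] == 1 ~ regime_vars[1],
      nr >= 2 & regime[species, min(2, nr)] == 1 ~ regime_vars[min(2, nr)],
      .default = "other"
    )
    ctx
  })
  context <- validate_context_table(context)

  # pairing from shared regimes
  pair_rows <- purrr::map_dfr(focal, function(f) {
    rs <- which(regime[f, ] == 1)
    an <- if (length(rs)) nonfocal[rowSums(regime[nonfocal, rs, drop = FALSE]) > 0]
          else character(0)
    if (length(an)) tibble::tibble(focal = f, analogue = an)
    else tibble::tibble(focal = f, analogue = NA_character_)
  })
  pairing <- as_analogue_pairing(pair_rows)

  structure(
    list(landmarks = landmarks, tree = tree, context = context,
         pairing = pairing, config = config,
         truth = list(regimes = regime, planted_loadings = U,
                      effect_size = eff, bm_sd = bm_sd, template = tpl,
                      focal_set = focal)),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic convergence study:", length(x$tree$tip.label), "species (",
      length(x$truth$focal_set), "focal ),", x$config$n_regimes,
      "planted regimes, seed", x$config$seed, "\n")
  invisible(x)
}

#' Correlation between recovered and planted shape loadings
#'
#' Procrustes alignment leaves shapes in an arbitrary common orientation,
#' so a recovered shape loading can only be compared with a planted one
#' after rotating into the template frame. This helper superimposes the
#' GPA consensus onto the (normalised) template, applies that rotation to
#' the recovered loading point-wise, and returns absolute vector
#' correlations with each planted loading.
#'
#' @param fit A `shape_gpa` of the study's landmarks.
#' @param study The `synthetic_study`.
#' @param loadings `p x k` recovered shape loadings (e.g. `pls$x_loadings`).
#' @return A matrix `k_recovered x n_regimes` of absolute correlations.
#' @export
planted_loading_correlation <- function(fit, study, loadings) {
  tpl <- normalise_config(study$truth$template)$points
  os <- optimal_superposition(fit$consensus, tpl, allow_reflection = TRUE)
  k <- nrow(tpl)
  rot <- function(v) {
    M <- matrix(v, k, 3, byrow = TRUE) %*% os$rotation
    as.vector(t(M))
  }
  L <- apply(as.matrix(loadings), 2, rot)
  abs(stats::cor(L, study$truth$planted_loadings))
}
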