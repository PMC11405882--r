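#' Contextual variable metadata
#'
#' The twelve contextual variables of body size, ecology and positional
#' behaviour used in the analyses: body mass (continuous, grams) plus eleven
#' ordinal scores. Ordinal ranges: pursuit of prey, habitat use
#' (ground-dwelling, arboreal), locomotion modes (scansorial, cursorial,
#' leaping, fossorial) and three-dimensional movement are scored 1--3;
#' aquatic habitat 1--4; agility 1--6 (extra slow to fast); posture 1--5
#' (fully orthograde to fully pronograde).
#'
#' @return A tibble with columns `variable`, `type` (`"continuous"` or
#'   `"ordinal"`), `min_level`, `max_level`.
#' @export
context_variables <- function() {
  tibble::tribble(
    ~variable,         ~type,        ~min_level, ~max_level,
    "body_mass",       "continuous", NA_real_,   NA_real_,
    "pursuit_of_prey", "ordinal",    1,          3,
    "aquatic",         "ordinal",    1,          4,
    "ground_dwelling", "ordinal",    1,          3,
    "arboreal",        "ordinal",    1,          3,
    "scansorial",      "ordinal",    1,          3,
    "cursorial",       "ordinal",    1,          3,
    "leaping",         "ordinal",    1,          3,
    "fossorial",       "ordinal",    1,          3,
    "moves_3d",        "ordinal",    1,          3,
    "agility",         "ordinal",    1,          6,
    "posture",         "ordinal",    1,          5
  )
}

#' Read landmark configurations from a long CSV file
#'
#' The long-CSV dialect has one row per point with header
#' `specimen_id,species_id,side,index,role,curve_id,x,y,z`. Point counts and
#' ordering are validated against the declared scheme, and specimens with a
#' wrong point count or non-finite coordinates are rejected.
#'
#' @param path Path to a CSV file.
#' @param scheme A `landmark_scheme` (default [labyrinth_scheme()]).
#' @return A long landmark tibble (class `tbl_df`), rows ordered by specimen
#'   then point index.
#' @seealso [write_landmarks()], [landmarks_to_array()]
#' @export
read_landmarks <- function(path, scheme = labyrinth_scheme()) {
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            specimen_id = readr::col_character(),
                            species_id = readr::col_character(),
                            side = readr::col_character(),
                            index = readr::col_integer(),
                            role = readr::col_character(),
                            curve_id = readr::col_character(),
                            x = readr::col_double(),
                            y = readr::col_double(),
                            z = readr::col_double()
                          ))
  bad <- which(!is.finite(data$x) | !is.finite(data$y) | !is.finite(data$z))
  if (length(bad)) {
    stop(sprintf("non-finite coordinate at row %d of '%s'", bad[1], path),
         call. = FALSE)
  }
  counts <- table(data$specimen_id)
  wrong <- counts != scheme$n_points
  if (any(wrong)) {
    id <- names(counts)[wrong][1]
    stop(sprintf(
      "scheme violation: specimen '%s' has %d points; scheme requires %d",
      id, counts[[id]], scheme$n_points), call. = FALSE)
  }
  dup <- unique(data[, c("specimen_id", "species_id")])
  if (anyDuplicated(dup$species_id)) {
    stop("duplicate species_id across specimens; one specimen per species is required",
         call. = FALSE)
  }
  data <- dplyr::arrange(data, factor(.data$specimen_id,
                                      levels = unique(data$specimen_id)),
                         .data$index)
  data
}

#' Write landmark configurations to a long CSV file
#'
#' @param data A long landmark tibble (see [read_landmarks()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(data, path) {
  cols <- c("specimen_id", "species_id", "side", "index", "role", "curve_id",
            "x", "y", "z")
  stopifnot(all(cols %in% names(data)))
  readr::write_csv(data[, cols], path)
  invisible(path)
}

#' Read the species-by-variable context table
#'
#' One row per species with a `species_id` column, the 12 contextual
#' variables of [context_variables()], and an optional `habitat_label`
#' column used only for plotting. Ordinal values are validated against
#' their level ranges; missing values and out-of-range scores are rejected.
#'
#' @param path Path to a CSV file.
#' @return A tibble with `species_id` first, then the 12 variables (and
#'   `habitat_label` if present), with attribute `"levels"` holding the
#'   variable metadata.
#' @export
read_context_table <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  validate_context_table(data)
}

#' Validate a context table against the declared measurement levels
#'
#' @param data A data frame with `species_id` and the 12 contextual
#'   variables.
#' @return The validated tibble (invisibly unchanged except for class).
#' @export
validate_context_table <- function(data) {
  meta <- context_variables()
  missing_cols <- setdiff(c("species_id", meta$variable), names(data))
  if (length(missing_cols)) {
    stop("context table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(data$species_id)) {
    stop("duplicate species_id in context table", call. = FALSE)
  }
  for (i in seq_len(nrow(meta))) {
    v <- meta$variable[i]
    vals <- data[[v]]
    if (anyNA(vals)) {
      stop(sprintf("missing value for variable '%s' (species '%s')",
                   v, data$species_id[which(is.na(vals))[1]]), call. = FALSE)
    }
    if (meta$type[i] == "continuous") {
      if (any(vals <= 0)) {
        stop(sprintf("non-positive body mass for species '%s'",
                     data$species_id[which(vals <= 0)[1]]), call. = FALSE)
      }
    } else {
      bad <- which(vals < meta$min_level[i] | vals > meta$max_level[i] |
                     vals != round(vals))
      if (length(bad)) {
        stop(sprintf(
          "ordinal value %g out of range [%d, %d] for variable '%s', species '%s'",
          vals[bad[1]], meta$min_level[i], meta$max_level[i], v,
          data$species_id[bad[1]]), call. = FALSE)
      }
    }
  }
  out <- tibble::as_tibble(data)
  keep <- c("species_id", meta$variable,
            intersect("habitat_label", names(data)))
  out <- out[, keep]
  attr(out, "levels") <- meta
  out
}

#' Write a context table to CSV
#' @param data A validated context tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_context_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Read an analogue-pairing table
#'
#' Long two-column format `focal,analogue`; a focal species with an empty
#' analogue field (or the literal `NA`) is recorded as an unpaired focal
#' species (e.g. a taxon with no living analogue). A species may appear as
#' analogue of several focal species; a species may not be both focal and
#' analogue.
#'
#' @param path Path to a CSV file with columns `focal`, `analogue`.
#' @return An object of class `analogue_pairing`: list with `focal_set`,
#'   `analogue_map` (named list focal -> character vector of analogues),
#'   `unpaired_focal`, and `pairs` (tibble of focal/analogue pairs).
#' @export
read_pairing <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("focal", "analogue") %in% names(data)) || nrow(data) == 0) {
    stop("pairing file must have columns 'focal' and 'analogue' and at least one row",
         call. = FALSE)
  }
  as_analogue_pairing(data)
}

#' Build an `analogue_pairing` from a focal/analogue pair table
#'
#' @param pairs A data frame with character columns `focal` and `analogue`
#'   (`NA` analogue marks an unpaired focal species).
#' @return An `analogue_pairing` object; see [read_pairing()].
#' @export
as_analogue_pairing <- function(pairs) {
  pairs <- tibble::as_tibble(pairs[, c("focal", "analogue")])
  pairs$analogue[pairs$analogue %in% c("", "n/a", "NA")] <- NA_character_
  focal_set <- unique(pairs$focal)
  real <- pairs[!is.na(pairs$analogue), ]
  overlap <- intersect(focal_set, real$analogue)
  if (length(overlap)) {
    stop("species listed both as focal and as analogue: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  analogue_map <- lapply(split(real$analogue, factor(real$focal, levels = focal_set)),
                         unique)
  unpaired <- focal_set[vapply(analogue_map, length, integer(1)) == 0]
  structure(
    list(focal_set = focal_set,
         analogue_map = analogue_map[lengths(analogue_map) > 0],
         unpaired_focal = unpaired,
         pairs = real),
    class = "analogue_pairing"
  )
}

#' @export
print.analogue_pairing <- function(x, ...) {
  cat("Analogue pairing:", length(x$focal_set), "focal species,",
      nrow(x$pairs), "focal-analogue pairs,",
      length(x$unpaired_focal), "unpaired focal\n")
  invisible(x)
}

#' Write an analogue pairing to CSV
#' @param pairing An `analogue_pairing`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairing <- function(pairing, path) {
  unpaired <- tibble::tibble(focal = pairing$unpaired_focal,
                             analogue = NA_character_)
  readr::write_csv(dplyr::bind_rows(pairing$pairs, unpaired), path)
  invisible(path)
}

#' Read an ultrametric phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] and checks branch lengths and ultrametricity.
#' Time trees are typically ultrametric only to rounding, so depth equality
#' is checked with a relative tolerance.
#'
#' @param path Path to a Newick file.
#' @param species Optional character vector; an error is raised if any of
#'   these species are missing from the tree's tips.
#' @param tol Relative tolerance on root-to-tip depths (default `1e-6`).
#' @param strict If `TRUE` (default) a non-ultrametric tree is an error,
#'   otherwise a warning.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path, species = NULL, tol = 1e-6, strict = TRUE) {
  tree <- ape::read.tree(path)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch lengths", call. = FALSE)
  }
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  rel <- diff(range(depths)) / max(depths)
  if (rel > tol) {
    msg <- sprintf("tree is not ultrametric (relative depth spread %.3g > %.3g)",
                   rel, tol)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  if (!is.null(species)) {
    missing_sp <- setdiff(species, tree$tip.label)
    if (length(missing_sp)) {
      stop("species absent from tree tips: ", paste(missing_sp, collapse = ", "),
           call. = FALSE)
    }
  }
  tree
}

#' Write an analysis report as JSON
#'
#' Reports carry a `report_type`, the parameters used (including the seed),
#' the results, and the package version, so a run can be reproduced from its
#' report alone.
#'
#' @param results A named list of results.
#' @param path Output path.
#' @param report_type Short report label.
#' @param parameters Named list of parameters (include the seed).
#' @return `path`, invisibly.
#' @export
write_report_json <- function(results, path, report_type, parameters = list()) {
  report <- list(
    report_type = report_type,
    parameters = parameters,
    results = results,
    software_version = as.character(utils::packageVersion("shapeconv"))
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
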