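#' Landmark scheme for the mammalian bony labyrinth
#'
#' A landmark scheme describes the fixed point order of a configuration:
#' which points are anatomical landmarks, which are semilandmarks, which
#' curve each semilandmark belongs to, and how curves are anchored on
#' anatomical landmarks for sliding.
#'
#' The default scheme has 13 anatomical landmarks and 111 semilandmarks
#' (124 points in total): midline curves of the three semicircular canals
#' (20 semilandmarks each), the common crus (5), the cochlear spiral (40),
#' and the outline of the oval window (6, a closed curve). Points are
#' ordered with the 13 anatomical landmarks first, then the semilandmarks
#' in curve order.
#'
#' @return An object of class `landmark_scheme`: a list with
#'   \describe{
#'     \item{n_points}{total number of points (124)}
#'     \item{roles}{character vector, `"anatomical"` or `"semilandmark"` per point}
#'     \item{curve_id}{character vector, curve label per point (`"none"` for
#'       points on no sliding curve)}
#'     \item{curves}{list of curve descriptors, each with `curve_id`, `path`
#'       (ordered point indices along the curve, anchors included),
#'       `sliders` (indices of points allowed to slide) and `closed` flag}
#'   }
#' @examples
#' sch <- labyrinth_scheme()
#' sch$n_points
#' table(sch$roles)
#' @export
labyrinth_scheme <- function() {
  n_lm <- 13L
  roles <- c(rep("anatomical", n_lm), rep("semilandmark", 111L))
  # semilandmark block indices (offset by the 13 anatomical landmarks)
  sl <- function(i) n_lm + i
  curves <- list(
    # ASC midline: LM 1 -> (2 SL ampulla) -> LM 2 -> (18 SL) -> LM 3
    list(curve_id = "ASC", path = c(1L, sl(1:2), 2L, sl(3:20), 3L),
         sliders = sl(1:20), closed = FALSE),
    # PSC midline: LM 6 -> (2 SL ampulla) -> LM 5 -> (18 SL) -> LM 3
    list(curve_id = "PSC", path = c(6L, sl(21:22), 5L, sl(23:40), 3L),
         sliders = sl(21:40), closed = FALSE),
    # common crus: LM 3 -> (5 SL) -> LM 4
    list(curve_id = "CC", path = c(3L, sl(41:45), 4L),
         sliders = sl(41:45), closed = FALSE),
    # LSC midline: LM 9 -> (2 SL ampulla) -> LM 8 -> (18 SL) -> LM 7
    list(curve_id = "LSC", path = c(9L, sl(46:47), 8L, sl(48:65), 7L),
         sliders = sl(46:65), closed = FALSE),
    # cochlear spiral: free basal end (apical side of the round window)
    # -> (40 SL) -> LM 10 at the apex
    list(curve_id = "cochlea", path = c(sl(66:105), 10L),
         sliders = sl(66:105), closed = FALSE),
    # oval window outline: closed, anchored on LM 13 and LM 12
    list(curve_id = "oval_window", path = c(13L, sl(106:108), 12L, sl(109:111)),
         sliders = sl(106:111), closed = TRUE)
  )
  curve_id <- rep("none", n_lm + 111L)
  for (cv in curves) curve_id[cv$sliders] <- cv$curve_id
  structure(
    list(n_points = n_lm + 111L, n_anatomical = n_lm, n_semilandmarks = 111L,
         roles = roles, curve_id = curve_id, curves = curves),
    class = "landmark_scheme"
  )
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("Landmark scheme:", x$n_anatomical, "anatomical landmarks +",
      x$n_semilandmarks, "semilandmarks (", x$n_points, "points )\n")
  for (cv in x$curves) {
    cat(sprintf("  curve %-12s %2d semilandmarks%s\n", cv$curve_id,
                length(cv$sliders), if (cv$closed) " (closed)" else ""))
  }
  invisible(x)
}

#' Sliding topology of a landmark scheme
#'
#' Extracts the curve/slider structure used by [slide_semilandmarks()].
#' Each sliding semilandmark belongs to exactly one curve; curve anchors are
#' anatomical landmarks (or free curve endpoints) and never move.
#'
#' @param scheme A `landmark_scheme`.
#' @return A tibble with one row per curve: `curve_id`, `n_sliders`,
#'   `closed`, and list-columns `path` and `sliders`.
#' @export
sliding_topology <- function(scheme = labyrinth_scheme()) {
  stopifnot(inherits(scheme, "landmark_scheme"))
  tibble::tibble(
    curve_id = vapply(scheme$curves, `[[`, character(1), "curve_id"),
    n_sliders = vapply(scheme$curves, function(cv) length(cv$sliders), integer(1)),
    closed = vapply(scheme$curves, `[[`, logical(1), "closed"),
    path = lapply(scheme$curves, `[[`, "path"),
    sliders = lapply(scheme$curves, `[[`, "sliders")
  )
}

# check that a point matrix conforms to a scheme; used by readers and gpa
validate_configuration <- function(points, scheme, id = "<config>") {
  if (nrow(points) != scheme$n_points) {
    stop(sprintf("configuration '%s' has %d points; scheme requires %d",
                 id, nrow(points), scheme$n_points), call. = FALSE)
  }
  if (!all(is.finite(points))) {
    stop(sprintf("configuration '%s' contains non-finite coordinates", id),
         call. = FALSE)
  }
  invisible(TRUE)
}
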