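# internal helpers

# derive a reproducible 32-bit sub-seed from a master seed and a stream id
substream_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(id) * 16807) %% 2147483647)
}

# run expr under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# landmark long tibble <-> n x k x 3 array ------------------------------

#' Convert a long landmark table to a 3D array
#'
#' @param data A long landmark tibble as returned by [read_landmarks()] or
#'   [simulate_study()]: columns `specimen_id`, `index`, `x`, `y`, `z`
#'   (plus any metadata).
#' @param scheme Optional `landmark_scheme` to validate point counts against.
#' @return A numeric array of dimension `n_specimens x n_points x 3` with
#'   dimnames on the first margin.
#' @export
landmarks_to_array <- function(data, scheme = NULL) {
  stopifnot(all(c("specimen_id", "index", "x", "y", "z") %in% names(data)))
  ids <- unique(data$specimen_id)
  split_rows <- split(seq_len(nrow(data)), factor(data$specimen_id, levels = ids))
  k <- length(split_rows[[1]])
  arr <- array(NA_real_, c(length(ids), k, 3),
               dimnames = list(ids, NULL, c("x", "y", "z")))
  for (i in seq_along(ids)) {
    rows <- split_rows[[i]]
    d <- data[rows, ]
    if (!is.null(scheme)) validate_configuration(cbind(d$x, d$y, d$z), scheme, ids[i])
    if (nrow(d) != k) {
      stop(sprintf("specimen '%s' has %d points; expected %d", ids[i], nrow(d), k),
           call. = FALSE)
    }
    d <- d[order(d$index), ]
    arr[i, , ] <- cbind(d$x, d$y, d$z)
  }
  arr
}

#' Convert a configuration array to a long landmark tibble
#'
#' @param arr `n x k x 3` array with specimen ids as first dimnames.
#' @param scheme A `landmark_scheme` supplying `role` and `curve_id`
#'   columns; defaults to [labyrinth_scheme()] when point counts match,
#'   otherwise roles are filled with `NA`.
#' @param species_id,side Optional per-specimen vectors (recycled from the
#'   specimen ids / `"unknown"`).
#' @return A long tibble with columns `specimen_id`, `species_id`, `side`,
#'   `index`, `role`, `curve_id`, `x`, `y`, `z`.
#' @export
array_to_landmarks <- function(arr, scheme = NULL, species_id = NULL, side = NULL) {
  n <- dim(arr)[1]; k <- dim(arr)[2]
  ids <- dimnames(arr)[[1]]
  if (is.null(ids)) ids <- sprintf("spec%02d", seq_len(n))
  if (is.null(scheme)) {
    sch <- labyrinth_scheme()
    if (sch$n_points == k) scheme <- sch
  }
  roles <- if (!is.null(scheme)) scheme$roles else rep(NA_character_, k)
  curve <- if (!is.null(scheme)) scheme$curve_id else rep(NA_character_, k)
  if (is.null(species_id)) species_id <- ids
  if (is.null(side)) side <- rep("unknown", n)
  purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(
      specimen_id = ids[i], species_id = species_id[i], side = side[i],
      index = seq_len(k), role = roles, curve_id = curve,
      x = arr[i, , 1], y = arr[i, , 2], z = arr[i, , 3]
    )
  })
}

flatten_shapes <- function(arr) {
  # n x k x 3 -> n x 3k matrix, coordinates interleaved per point (x,y,z)
  n <- dim(arr)[1]; k <- dim(arr)[2]
  out <- matrix(0, n, 3 * k, dimnames = list(dimnames(arr)[[1]], NULL))
  out[, seq(1, 3 * k, 3)] <- arr[, , 1]
  out[, seq(2, 3 * k, 3)] <- arr[, , 2]
  out[, seq(3, 3 * k, 3)] <- arr[, , 3]
  out
}

unflatten_shapes <- function(mat) {
  n <- nrow(mat); k <- ncol(mat) / 3
  arr <- array(0, c(n, k, 3), dimnames = list(rownames(mat), NULL, c("x", "y", "z")))
  arr[, , 1] <- mat[, seq(1, 3 * k, 3)]
  arr[, , 2] <- mat[, seq(2, 3 * k, 3)]
  arr[, , 3] <- mat[, seq(3, 3 * k, 3)]
  arr
}
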