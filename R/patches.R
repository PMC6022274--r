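#' Partition a candidate region into non-overlapping patches
#'
#' Cuts the 300 x 300 region into `n = (300/M)^2` non-overlapping `M x M`
#' patches and vectorizes each one lexicographically (row-major within the
#' patch). Patches are ordered row-major over the grid. The operation is
#' exactly invertible by [reassemble_patches()].
#'
#' @param region A [candidate_region()] or a bare 300 x 300 matrix.
#' @param M Patch side in pixels; must divide 300 (the method's usual values
#'   are 5, 10, 30, 50, 100).
#' @return An object of class `patch_grid`: a list with `M`, `n`, `d = M^2`,
#'   `R` (d x n matrix, one vectorized patch per column), `grid_index`
#'   (n x 2 matrix of grid row/col per column), and `source` (candidate id).
#' @export
partition_patches <- function(region, M) {
  px <- if (inherits(region, "candidate_region")) region$pixels else region
  source <- if (inherits(region, "candidate_region")) region$source_id else "matrix"
  stopifnot(is.matrix(px), all(dim(px) == c(300L, 300L)))
  M <- as.integer(M)
  if (M < 1L || 300L %% M != 0L) {
    stop("patch side M must divide 300", call. = FALSE)
  }
  g <- 300L %/% M
  n <- g * g
  d <- M * M
  # split the region into an M x g x M x g array; patch (i,j) is [, i, , j].
  # Row-major vectorization of a patch = as.vector(t(patch)).
  a <- array(px, dim = c(M, g, M, g))
  # reorder to (col-within-patch, row-within-patch, grid-col, grid-row) so a
  # straight reshape yields row-major patch vectors in row-major grid order
  a <- aperm(a, c(3L, 1L, 4L, 2L))
  R <- matrix(a, nrow = d, ncol = n)
  grid_index <- cbind(row = rep(seq_len(g), each = g),
                      col = rep(seq_len(g), times = g))
  structure(list(M = M, n = n, d = d, R = R, grid_index = grid_index,
                 source = source),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %s: %d patches of %d x %d px (d = %d)\n",
              x$source, x$n, x$M, x$M, x$d))
  invisible(x)
}

#' Reassemble a region from (possibly replaced) patch columns
#'
#' Places column `i` of `replacement` at the grid slot recorded for column
#' `i` of the grid. With `replacement = grid$R` this is the exact inverse of
#' [partition_patches()].
#'
#' @param grid A `patch_grid`.
#' @param replacement d x n matrix of patch columns (defaults to `grid$R`).
#' @return A 300 x 300 numeric matrix.
#' @export
reassemble_patches <- function(grid, replacement = grid$R) {
  stopifnot(inherits(grid, "patch_grid"))
  if (!is.matrix(replacement) || !all(dim(replacement) == dim(grid$R))) {
    stop("replacement must have the same shape as grid$R", call. = FALSE)
  }
  M <- grid$M
  out <- matrix(0, 300L, 300L)
  for (i in seq_len(grid$n)) {
    gr <- grid$grid_index[i, 1]; gc <- grid$grid_index[i, 2]
    patch <- matrix(replacement[, i], M, M, byrow = TRUE)
    out[((gr - 1L) * M + 1L):(gr * M), ((gc - 1L) * M + 1L):(gc * M)] <- patch
  }
  out
}

#' Pool patch grids into a corpus
#'
#' Concatenates the patch columns of several grids (all with the same patch
#' side) into one d x N corpus matrix, keeping per-column provenance. The
#' corpus is the data matrix from which the dictionary is selected.
#'
#' @param grids A list of `patch_grid` objects.
#' @return An object of class `patch_corpus`: a list with `X` (d x N), `N`,
#'   `M`, `d`, and `provenance` (a tibble with `candidate_id`, `grid_row`,
#'   `grid_col` per column).
#' @export
build_corpus <- function(grids) {
  stopifnot(is.list(grids))
  if (length(grids) == 0L) {
    return(structure(list(X = matrix(numeric(0), 0, 0), N = 0L, M = NA_integer_,
                          d = NA_integer_,
                          provenance = tibble::tibble(candidate_id = character(),
                                                      grid_row = integer(),
                                                      grid_col = integer())),
                     class = "patch_corpus"))
  }
  stopifnot(all(vapply(grids, inherits, logical(1), "patch_grid")))
  Ms <- vapply(grids, `[[`, integer(1), "M")
  if (length(unique(Ms)) != 1L) {
    stop("all grids must share the same patch side M", call. = FALSE)
  }
  X <- do.call(cbind, lapply(grids, `[[`, "R"))
  prov <- dplyr::bind_rows(lapply(grids, function(g) {
    tibble::tibble(candidate_id = g$source,
                   grid_row = as.integer(g$grid_index[, 1]),
                   grid_col = as.integer(g$grid_index[, 2]))
  }))
  structure(list(X = X, N = ncol(X), M = Ms[1], d = grids[[1]]$d,
                 provenance = prov),
            class = "patch_corpus")
}

#' @export
print.patch_corpus <- function(x, ...) {
  cat(sprintf("<patch_corpus> N = %d patches (M = %s, d = %s) from %d candidates\n",
              x$N, x$M, x$d, length(unique(x$provenance$candidate_id))))
  invisible(x)
}

#' Subsample a corpus to at most `max_cols` columns
#'
#' The self-representation problem scales with the square of the corpus
#' size, so large corpora are subsampled (uniformly, without replacement,
#' deterministically under `seed`) before dictionary selection.
#'
#' @param corpus A `patch_corpus`.
#' @param max_cols Column cap; the default keeps desk-scale problems
#'   tractable.
#' @param seed Integer seed for the subsample.
#' @return A `patch_corpus` with `N <= max_cols`.
#' @export
subsample_corpus <- function(corpus, max_cols = 5000L, seed = 1L) {
  stopifnot(inherits(corpus, "patch_corpus"))
  if (corpus$N <= max_cols) return(corpus)
  keep <- withr::with_seed(seed, sort(sample.int(corpus$N, max_cols)))
  structure(list(X = corpus$X[, keep, drop = FALSE], N = length(keep),
                 M = corpus$M, d = corpus$d,
                 provenance = corpus$provenance[keep, ]),
            class = "patch_corpus")
}
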