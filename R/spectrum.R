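#' Nearest dictionary atom per patch
#'
#' For each patch column, the index of the atom minimizing the Euclidean
#' distance; exact ties are broken by the lowest atom index.
#'
#' @param patches d x n matrix of patch columns (or a d-vector for a single
#'   patch).
#' @param dict An `atom_dictionary`.
#' @return Integer vector of atom indices, one per patch.
#' @export
nearest_atoms <- function(patches, dict) {
  stopifnot(inherits(dict, "atom_dictionary"))
  if (!is.matrix(patches)) patches <- matrix(patches, ncol = 1L)
  if (nrow(patches) != nrow(dict$V)) {
    stop("patch dimension does not match dictionary atom dimension",
         call. = FALSE)
  }
  V <- dict$V
  # squared distances via the expansion ||r||^2 - 2 r'v + ||v||^2
  d2 <- outer(colSums(patches^2), colSums(V^2), `+`) -
    2 * crossprod(patches, V)
  max.col(-d2, ties.method = "first")
}

#' Local feature spectrum of a candidate
#'
#' Assigns every patch of the candidate to its nearest dictionary atom and
#' counts how often each atom is used. The resulting length-`Dsize` count
#' vector (the "spectrum") is the candidate's feature: it depends only on
#' which local features occur, not where, so it is invariant to any
#' permutation of the patches.
#'
#' @param grid A `patch_grid` (see [partition_patches()]).
#' @param dict An `atom_dictionary` with matching atom dimension.
#' @return An object of class `spectrum_feature`: `counts` (integer,
#'   length `Dsize`, summing to `grid$n`), `assignment` (per-patch atom
#'   index), `n`, and `candidate_id`.
#' @export
spectrum <- function(grid, dict) {
  stopifnot(inherits(grid, "patch_grid"))
  assignment <- nearest_atoms(grid$R, dict)
  counts <- tabulate(assignment, nbins = dict$Dsize)
  structure(list(counts = as.integer(counts), n = grid$n,
                 assignment = assignment, candidate_id = grid$source),
            class = "spectrum_feature")
}

#' @export
print.spectrum_feature <- function(x, ...) {
  cat(sprintf("<spectrum_feature> %s: %d patches over %d atoms (%d used)\n",
              x$candidate_id, x$n, length(x$counts), sum(x$counts > 0)))
  invisible(x)
}

#' Spectrum feature table for a set of candidates
#'
#' Computes the local feature spectrum of every candidate and returns a wide
#' tibble: one row per candidate, one `atom_*` count column per dictionary
#' atom, plus `candidate_id` and `label`.
#'
#' @param regions List of [candidate_region()] objects.
#' @param dict An `atom_dictionary` built at patch side `M`.
#' @param M Patch side; defaults to the dictionary's recorded `M`.
#' @return A tibble of class `lfsa_features` with columns `candidate_id`,
#'   `label`, `atom_001` ... `atom_<Dsize>`.
#' @export
spectrum_features <- function(regions, dict, M = dict$M) {
  stopifnot(is.list(regions), inherits(dict, "atom_dictionary"))
  if (is.na(M)) stop("patch side M must be given", call. = FALSE)
  rows <- purrr::imap(regions, function(reg, i) {
    g <- partition_patches(reg, M)
    sp <- spectrum(g, dict)
    c(list(candidate_id = if (inherits(reg, "candidate_region")) reg$source_id
           else paste0("candidate-", i),
           label = if (inherits(reg, "candidate_region")) reg$label else "unknown"),
      stats::setNames(as.list(sp$counts),
                      sprintf("atom_%03d", seq_along(sp$counts))))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("lfsa_features", class(out))
  out
}

#' Extract the numeric feature matrix from a feature table
#' @param features A tibble from [spectrum_features()] (or any tibble whose
#'   non-feature columns are `candidate_id` and `label`).
#' @return Numeric matrix, one row per candidate.
#' @export
feature_matrix <- function(features) {
  keep <- setdiff(names(features), c("candidate_id", "label"))
  as.matrix(features[keep])
}

#' Nearest-atom reconstruction of a candidate
#'
#' Replaces every patch by its nearest dictionary atom and reassembles the
#' region. Returns the reconstruction, the signed error image
#' (original minus reconstruction), and the per-pixel mean squared error.
#'
#' @param grid A `patch_grid`.
#' @param dict An `atom_dictionary`.
#' @return An object of class `reconstruction_report`: `reconstructed`,
#'   `error_image` (both 300 x 300), `mse`, `candidate_id`.
#' @export
reconstruct <- function(grid, dict) {
  stopifnot(inherits(grid, "patch_grid"))
  assignment <- nearest_atoms(grid$R, dict)
  recon <- reassemble_patches(grid, dict$V[, assignment, drop = FALSE])
  orig <- reassemble_patches(grid)
  err <- orig - recon
  structure(list(reconstructed = recon, error_image = err,
                 mse = mean(err^2), candidate_id = grid$source),
            class = "reconstruction_report")
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat(sprintf("<reconstruction_report> %s: mse = %.6g\n", x$candidate_id, x$mse))
  invisible(x)
}

#' Dataset-level reconstruction error
#'
#' The mean over candidates of the per-pixel mean squared error between each
#' original region and its nearest-atom reconstruction. Smaller is better; a
#' richer dictionary can only lower it.
#'
#' @param reports List of `reconstruction_report` objects (or their `mse`
#'   values as a numeric vector).
#' @return Scalar mean reconstruction error.
#' @export
r_error <- function(reports) {
  if (is.numeric(reports)) {
    mses <- reports
  } else {
    if (!is.list(reports) || length(reports) < 1L) {
      stop("need at least one reconstruction report", call. = FALSE)
    }
    mses <- vapply(reports, function(r) {
      stopifnot(inherits(r, "reconstruction_report"))
      r$mse
    }, numeric(1))
  }
  if (length(mses) < 1L) stop("need at least one reconstruction", call. = FALSE)
  mean(mses)
}

#' Reconstruction error of a candidate set under a dictionary
#'
#' Convenience wrapper: partitions each region, reconstructs it from the
#' dictionary, and averages the per-region mean squared errors.
#'
#' @param regions List of [candidate_region()] objects.
#' @param dict An `atom_dictionary`.
#' @param M Patch side; defaults to the dictionary's recorded `M`.
#' @return Scalar reconstruction error.
#' @export
reconstruction_error <- function(regions, dict, M = dict$M) {
  stopifnot(length(regions) >= 1L)
  mean(vapply(regions, function(reg) {
    reconstruct(partition_patches(reg, M), dict)$mse
  }, numeric(1)))
}
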