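#' Row-wise l2,1 norm
#'
#' `sum_i ||B_i.||_2`: the sum of the Euclidean norms of the rows of `B`.
#' Penalizing it drives whole rows of the self-representation matrix to zero,
#' which is what turns representation into sample selection.
#'
#' @param B Numeric matrix (a vector is treated as a single row).
#' @return Scalar.
#' @export
l21_norm <- function(B) {
  if (!is.matrix(B)) B <- matrix(B, nrow = 1L)
  sum(sqrt(rowSums(B^2)))
}

#' Self-representation selection objective
#'
#' `0.5 * ||X - X B||_F^2 + lambda * ||B||_{2,1}`. Minimizing over `B` makes
#' the corpus reconstruct itself from few of its own columns: the surviving
#' (nonzero) rows of `B` index the most representative patches.
#'
#' @param X d x N corpus matrix.
#' @param B N x N representation matrix.
#' @param lambda Nonnegative regularization weight.
#' @return Scalar objective value.
#' @export
selection_objective <- function(X, B, lambda) {
  stopifnot(lambda >= 0, ncol(X) == nrow(B), nrow(B) == ncol(B))
  0.5 * sum((X - X %*% B)^2) + lambda * l21_norm(B)
}

#' Proximal operator of the l2,1 norm (row-wise group soft threshold)
#'
#' Each row is shrunk toward zero: `row <- max(0, 1 - tau/||row||_2) * row`.
#' Rows with norm below `tau` vanish entirely; zero rows stay zero.
#'
#' @param B Numeric matrix.
#' @param tau Nonnegative threshold.
#' @return Matrix of the same shape.
#' @export
prox_l21 <- function(B, tau) {
  stopifnot(tau >= 0)
  if (tau == 0) return(B)
  nrm <- sqrt(rowSums(B^2))
  scl <- pmax(0, 1 - tau / pmax(nrm, .Machine$double.xmin))
  B * scl
}

# largest eigenvalue of X'X by power iteration on v -> X'(Xv)
power_lmax <- function(X, iters = 50L, tol = 1e-8) {
  N <- ncol(X)
  v <- rep(1 / sqrt(N), N)
  lam <- 0
  for (i in seq_len(iters)) {
    w <- crossprod(X, X %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v_new <- as.vector(w / nw)
    lam_new <- sum(v_new * crossprod(X, X %*% v_new))
    if (abs(lam_new - lam) <= tol * (1 + abs(lam_new))) {
      return(lam_new)
    }
    lam <- lam_new
    v <- v_new
  }
  lam
}

#' Default regularization weight
#'
#' One tenth of the smallest `lambda` that zeroes `B` entirely (the largest
#' row norm of `X'X`, by the optimality condition at `B = 0`). Keeps a
#' useful number of nonzero rows across corpus scales, since it inherits the
#' data's scale automatically.
#'
#' @param X d x N corpus matrix.
#' @param frac Fraction of the all-zero threshold (default 0.1).
#' @return Scalar lambda.
#' @export
auto_lambda <- function(X, frac = 0.1) {
  A <- crossprod(X)
  frac * max(sqrt(rowSums(A^2)))
}

#' Solve the l2,1-regularized self-representation problem
#'
#' Minimizes `0.5 ||X - X B||_F^2 + lambda ||B||_{2,1}` by monotone
#' accelerated proximal gradient descent (FISTA with an objective guard, so
#' the recorded objective trace is non-increasing). The gradient step uses a
#' constant step size `1/L` with `L` the largest eigenvalue of `X'X`
#' estimated by power iteration. Iteration stops when the relative objective
#' change drops below `tol` or after `max_iter` iterations.
#'
#' @param X d x N corpus matrix (or a `patch_corpus`).
#' @param lambda Regularization weight; `"auto"` for [auto_lambda()].
#' @param max_iter Maximum iterations.
#' @param tol Relative objective-change stopping tolerance.
#' @param B_init Optional N x N warm-start matrix (e.g. the solution at a
#'   nearby lambda).
#' @return An object of class `selection_result`: `B` (N x N), `weights`
#'   (row norms of `B`), `lambda`, `objective_trace`, `iterations`,
#'   `converged`.
#' @export
solve_selection <- function(X, lambda = "auto", max_iter = 500L, tol = 1e-6,
                            B_init = NULL) {
  if (inherits(X, "patch_corpus")) X <- X$X
  stopifnot(is.matrix(X), ncol(X) >= 1L)
  if (any(!is.finite(X))) stop("corpus contains non-finite values", call. = FALSE)
  if (identical(lambda, "auto")) lambda <- auto_lambda(X)
  stopifnot(is.numeric(lambda), lambda >= 0)
  N <- ncol(X)

  L <- power_lmax(X)
  if (L <= 0) L <- 1  # all-zero corpus: any step size works
  step <- 1 / L

  obj <- function(B) 0.5 * sum((X - X %*% B)^2) + lambda * l21_norm(B)

  B <- if (is.null(B_init)) matrix(0, N, N) else B_init
  stopifnot(all(dim(B) == c(N, N)))
  Y <- B                     # extrapolation point
  fB <- obj(B)
  trace <- fB
  t_k <- 1
  converged <- FALSE
  iters <- 0L

  for (k in seq_len(max_iter)) {
    iters <- k
    G <- crossprod(X, X %*% Y - X)          # gradient of the smooth part at Y
    Z <- prox_l21(Y - step * G, step * lambda)
    fZ <- obj(Z)
    if (fZ <= fB) {
      # monotone FISTA: accept the proximal point, extrapolate past it
      t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
      Y <- Z + ((t_k - 1) / t_next) * (Z - B)
      rel <- (fB - fZ) / (1 + abs(fB))
      B <- Z; fB <- fZ; t_k <- t_next
      trace <- c(trace, fB)
      if (k > 1L && rel < tol) {
        converged <- TRUE
        break
      }
    } else {
      # overshoot: keep the old iterate and restart the momentum from it;
      # the next step is then a plain proximal-gradient step, which cannot
      # increase the objective
      t_k <- 1
      Y <- B
      trace <- c(trace, fB)
    }
  }

  weights <- sqrt(rowSums(B^2))
  structure(
    list(B = B, weights = weights, lambda = lambda,
         objective_trace = trace, iterations = iters, converged = converged),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> N = %d, lambda = %.4g, %d iterations (%s), %d nonzero rows\n",
    length(x$weights), x$lambda, x$iterations,
    if (x$converged) "converged" else "max_iter reached",
    sum(x$weights > 0)))
  invisible(x)
}

#' @rdname solve_selection
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per corpus column (`column`,
#'   `weight`, `selected_rank`); `glance()`: a one-row tibble of fit summary.
#' @export
tidy.selection_result <- function(x, ...) {
  ord <- order(-x$weights, seq_along(x$weights))
  rank <- integer(length(x$weights))
  rank[ord] <- seq_along(ord)
  tibble::tibble(column = seq_along(x$weights), weight = x$weights,
                 selected_rank = rank)
}

#' @rdname solve_selection
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(
    n_columns = length(x$weights),
    nonzero_rows = sum(x$weights > 0),
    lambda = x$lambda,
    objective = x$objective_trace[length(x$objective_trace)],
    iterations = x$iterations,
    converged = x$converged
  )
}

new_dictionary <- function(V, atom_sources, method, M = NA_integer_,
                           lambda = NA_real_) {
  structure(list(V = V, Dsize = ncol(V), atom_sources = atom_sources,
                 method = method, M = M, lambda = lambda),
            class = "atom_dictionary")
}

#' @export
print.atom_dictionary <- function(x, ...) {
  cat(sprintf("<atom_dictionary> %d atoms of dimension %d (method: %s)\n",
              x$Dsize, nrow(x$V), x$method))
  invisible(x)
}

#' Rank corpus columns by weight and select the dictionary
#'
#' Sorts the per-row weights of a [solve_selection()] fit in descending
#' order and takes the corpus columns with the `Dsize` largest weights as
#' atoms. Ties (including the all-zero tail) are broken by lower column
#' index. If fewer than `Dsize` rows are nonzero, selection proceeds into the
#' zero-weight rows with a warning.
#'
#' @param result A `selection_result`.
#' @param X The corpus the result was fitted on (d x N matrix or
#'   `patch_corpus`).
#' @param Dsize Number of atoms, `1 <= Dsize <= N`.
#' @return An `atom_dictionary` with `method = "sparse"`.
#' @export
rank_and_select <- function(result, X, Dsize) {
  stopifnot(inherits(result, "selection_result"))
  M <- NA_integer_
  if (inherits(X, "patch_corpus")) { M <- X$M; X <- X$X }
  N <- ncol(X)
  stopifnot(length(result$weights) == N, Dsize >= 1, Dsize <= N)
  if (sum(result$weights > 0) < Dsize) {
    warning("Dsize exceeds the number of nonzero-weight rows; ",
            "filling with zero-weight columns by index order")
  }
  ord <- order(-result$weights, seq_len(N))
  idx <- ord[seq_len(Dsize)]
  new_dictionary(X[, idx, drop = FALSE], idx, "sparse", M = M,
                 lambda = result$lambda)
}

#' Convenience wrapper: sparse dictionary from a corpus
#'
#' Runs [solve_selection()] then [rank_and_select()]. With
#' `lambda = "auto"` the regularization weight is found by continuation: the
#' solver starts at a tenth of the all-zero threshold (see [auto_lambda()])
#' and, while fewer than `Dsize` rows survive, lambda is divided by 4 and the
#' problem re-solved warm-started from the previous solution. On highly
#' redundant corpora a fixed fraction can leave far fewer selectable atoms
#' than requested; the continuation guarantees the selection actually
#' supports `Dsize` atoms whenever the corpus does.
#'
#' @inheritParams solve_selection
#' @inheritParams rank_and_select
#' @param min_frac Smallest fraction of the all-zero threshold tried by the
#'   continuation.
#' @return An `atom_dictionary` with `method = "sparse"`.
#' @export
sparse_dictionary <- function(X, Dsize, lambda = "auto", max_iter = 500L,
                              tol = 1e-6, min_frac = 1e-5) {
  res <- solve_selection_for(X, Dsize, lambda = lambda, max_iter = max_iter,
                             tol = tol, min_frac = min_frac)
  rank_and_select(res, X, Dsize)
}

# continuation used by sparse_dictionary() and run_grid(): decrease lambda
# (warm-started) until at least Dsize rows survive
solve_selection_for <- function(X, Dsize, lambda = "auto", max_iter = 500L,
                                tol = 1e-6, min_frac = 1e-5) {
  Xm <- if (inherits(X, "patch_corpus")) X$X else X
  if (!identical(lambda, "auto")) {
    return(solve_selection(X, lambda = lambda, max_iter = max_iter, tol = tol))
  }
  frac <- 0.1
  lam0 <- auto_lambda(Xm, 1)
  res <- solve_selection(X, lambda = frac * lam0, max_iter = max_iter,
                         tol = tol)
  while (sum(res$weights > 0) < min(Dsize, ncol(Xm)) && frac / 4 >= min_frac) {
    frac <- frac / 4
    res <- solve_selection(X, lambda = frac * lam0, max_iter = max_iter,
                           tol = tol, B_init = res$B)
  }
  res
}

#' K-means baseline dictionary
#'
#' Atoms are the `Dsize` cluster centroids of the corpus columns (not corpus
#' columns themselves). Empty clusters are re-seeded from the point farthest
#' from its centroid and the clustering re-run. Deterministic under `seed`.
#'
#' @param X d x N corpus matrix or `patch_corpus`.
#' @param Dsize Number of centroids.
#' @param seed Integer seed.
#' @return An `atom_dictionary` with `method = "kmeans"` and
#'   `atom_sources = NA` (centroids are synthesized, not selected).
#' @export
kmeans_dictionary <- function(X, Dsize, seed = 1L) {
  M <- NA_integer_
  if (inherits(X, "patch_corpus")) { M <- X$M; X <- X$X }
  N <- ncol(X)
  stopifnot(Dsize >= 1, Dsize <= N)
  pts <- t(X)
  centers <- withr::with_seed(seed, {
    if (Dsize == 1L) {
      matrix(colMeans(pts), nrow = 1L)
    } else {
      # initial centers: a random draw, deduplicated so kmeans() accepts it
      perm <- sample.int(N)
      uniq <- perm[!duplicated(pts[perm, , drop = FALSE])]
      if (length(uniq) < Dsize) {
        stop("corpus has fewer than Dsize distinct columns", call. = FALSE)
      }
      init <- pts[uniq[seq_len(Dsize)], , drop = FALSE]
      for (attempt in 1:10) {
        km <- suppressWarnings(
          kmeans(pts, centers = init, iter.max = 100L, algorithm = "Lloyd")
        )
        sizes <- km$size
        if (all(sizes > 0L)) break
        # re-seed empty clusters from the points farthest from their centroid
        d2 <- rowSums((pts - km$centers[km$cluster, , drop = FALSE])^2)
        init <- km$centers
        for (e in which(sizes == 0L)) {
          far <- which.max(d2)
          init[e, ] <- pts[far, ]
          d2[far] <- -Inf
        }
      }
      km$centers
    }
  })
  new_dictionary(t(centers), rep(NA_integer_, Dsize), "kmeans", M = M)
}

#' Random-selection baseline dictionary
#'
#' Atoms are `Dsize` distinct corpus columns sampled uniformly without
#' replacement; deterministic under `seed`.
#'
#' @inheritParams kmeans_dictionary
#' @return An `atom_dictionary` with `method = "random"`.
#' @export
random_dictionary <- function(X, Dsize, seed = 1L) {
  M <- NA_integer_
  if (inherits(X, "patch_corpus")) { M <- X$M; X <- X$X }
  N <- ncol(X)
  stopifnot(Dsize >= 1, Dsize <= N)
  idx <- withr::with_seed(seed, sample.int(N, Dsize))
  new_dictionary(X[, idx, drop = FALSE], idx, "random", M = M)
}
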