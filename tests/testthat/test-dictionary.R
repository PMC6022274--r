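test_that("l2,1 norm matches its definition", {
  expect_equal(l21_norm(rbind(c(3, 4), c(0, 0))), 5)
  expect_equal(l21_norm(diag(7)), 7)
  # single-row case: reduces to the l2 norm of that row
  expect_equal(l21_norm(c(3, 4)), 5)
  # equivalence with the l1 norm of the vector of row norms
  B <- matrix(rnorm(30), 5, 6)
  expect_equal(l21_norm(B), sum(abs(sqrt(rowSums(B^2)))))
})

test_that("selection objective evaluates its closed form", {
  X <- matrix(rnorm(12), 3, 4)
  lam <- 0.7
  expect_equal(selection_objective(X, diag(4), lam), lam * 4)
  expect_equal(selection_objective(X, matrix(0, 4, 4), lam),
               0.5 * sum(X^2))
  X2 <- diag(2)
  expect_equal(selection_objective(X2, matrix(0, 2, 2), 1), 1.0)
  expect_error(selection_objective(X, diag(3), lam))
})

test_that("prox_l21 performs row-wise group soft thresholding", {
  expect_equal(prox_l21(matrix(c(3, 4), 1), 2.5), matrix(c(1.5, 2), 1))
  expect_equal(prox_l21(matrix(c(0.6, 0.8), 1), 2), matrix(c(0, 0), 1))
  B <- matrix(rnorm(40), 8, 5)
  expect_identical(prox_l21(B, 0), B)
  # analytic form on random rows
  tau <- 0.3
  P <- prox_l21(B, tau)
  for (i in 1:8) {
    nrm <- sqrt(sum(B[i, ]^2))
    expect_equal(P[i, ], pmax(0, 1 - tau / nrm) * B[i, ], tolerance = 1e-12)
  }
  # zero rows stay zero
  B[3, ] <- 0
  expect_true(all(prox_l21(B, tau)[3, ] == 0))
})

test_that("solver handles the analytic boundary cases", {
  set.seed(42)
  X <- matrix(rnorm(5 * 8), 5, 8)

  # lambda = 0: perfect self-representation is optimal
  s0 <- solve_selection(X, lambda = 0, max_iter = 5000, tol = 1e-12)
  expect_lt(utils::tail(s0$objective_trace, 1), 1e-8)

  # lambda above the all-zero threshold: B = 0 is optimal (subgradient
  # condition ||(X'X)_i.||_2 <= lambda for every row)
  lam_max <- max(sqrt(rowSums(crossprod(X)^2)))
  s1 <- solve_selection(X, lambda = lam_max * 1.01, max_iter = 200)
  expect_true(all(s1$weights == 0))
  expect_equal(utils::tail(s1$objective_trace, 1), 0.5 * sum(X^2))
})

test_that("solver matches the independent ADMM oracle on random instances", {
  set.seed(7)
  for (trial in 1:5) {
    d <- sample(3:8, 1); N <- sample(5:15, 1)
    X <- matrix(rnorm(d * N), d, N)
    lam <- sample(c(0.1, 0.5, 1), 1)
    mine <- solve_selection(X, lambda = lam, max_iter = 20000, tol = 1e-14)
    oracle <- oracle_solve_selection(X, lam)
    f <- utils::tail(mine$objective_trace, 1)
    expect_lt(abs(f - oracle$objective) / (1 + abs(oracle$objective)), 1e-6)
  }
})

test_that("objective trace is monotone and beats trivial feasible points", {
  set.seed(11)
  X <- matrix(runif(6 * 12), 6, 12)
  lam <- auto_lambda(X, 0.05)
  s <- solve_selection(X, lambda = lam, max_iter = 2000, tol = 1e-10)
  expect_true(all(diff(s$objective_trace) <= 1e-12))
  f <- utils::tail(s$objective_trace, 1)
  expect_lte(f, selection_objective(X, matrix(0, 12, 12), lam))
  expect_lte(f, selection_objective(X, diag(12), lam))
  # weights are the row norms of B
  expect_equal(s$weights, sqrt(rowSums(s$B^2)))
  expect_error(solve_selection(matrix(c(1, NA), 1, 2), 0.1), "finite")
})

test_that("row support shrinks as lambda grows", {
  fx <- make_prototype_corpus(31, K = 4L, d = 20L, reps = 10L)
  lam0 <- auto_lambda(fx$X, 1)
  nnz <- vapply(c(0.005, 0.02, 0.08, 0.3) * lam0, function(lam) {
    sum(solve_selection(fx$X, lam, max_iter = 3000, tol = 1e-10)$weights > 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 1))  # non-increasing within one row of slack
})

test_that("scaling X by c and lambda by c^2 leaves the optimum unchanged", {
  set.seed(19)
  X <- matrix(rnorm(10 * 8), 10, 8)  # overdetermined: unique optimum
  lam <- 0.4
  s1 <- solve_selection(X, lam, max_iter = 20000, tol = 1e-14)
  s2 <- solve_selection(3 * X, 9 * lam, max_iter = 20000, tol = 1e-14)
  expect_equal(s1$B, s2$B, tolerance = 1e-5)
})

test_that("atoms are the top-weighted corpus columns with deterministic ties", {
  res <- structure(list(B = diag(c(0.1, 0.9, 0.5)),
                        weights = c(0.1, 0.9, 0.5), lambda = 1,
                        objective_trace = c(1, 0), iterations = 1L,
                        converged = TRUE),
                   class = "selection_result")
  X <- matrix(seq_len(6), 2, 3)
  dict <- rank_and_select(res, X, 2)
  expect_equal(dict$atom_sources, c(2L, 3L))
  expect_identical(dict$V, X[, c(2, 3)])
  expect_equal(dict$method, "sparse")

  all3 <- rank_and_select(res, X, 3)
  expect_equal(all3$atom_sources, c(2L, 3L, 1L))

  res$weights <- c(0.9, 0, 0)
  res$B <- diag(c(0.9, 0, 0))
  expect_warning(rank_and_select(res, X, 2), "zero-weight")
})

test_that("sparse selection recovers planted prototypes", {
  fx <- make_prototype_corpus(101)
  sel <- solve_selection(fx$X, auto_lambda(fx$X), max_iter = 20000,
                         tol = 1e-12)
  dict <- suppressWarnings(rank_and_select(sel, fx$X, 5))
  expect_equal(sort(unique(atom_prototype_map(dict, fx$protos))), 1:5)
})

test_that("kmeans dictionary gives centroids, handling degenerate corpora", {
  X <- matrix(runif(40), 8, 5)
  one <- kmeans_dictionary(X, 1, seed = 2)
  expect_equal(as.vector(one$V), rowMeans(X))
  expect_equal(one$method, "kmeans")

  # groups of identical columns are recovered exactly
  G <- matrix(runif(8 * 3), 8, 3)
  Xg <- G[, rep(1:3, each = 4)]
  km <- kmeans_dictionary(Xg, 3, seed = 5)
  reorder <- atom_prototype_map(km, G)
  expect_equal(sort(reorder), 1:3)
  expect_equal(km$V[, order(reorder)], G, ignore_attr = TRUE)

  expect_identical(kmeans_dictionary(X, 2, seed = 9)$V,
                   kmeans_dictionary(X, 2, seed = 9)$V)
})

test_that("random dictionaries sample distinct columns deterministically", {
  X <- matrix(rnorm(6 * 10), 6, 10)
  all10 <- random_dictionary(X, 10, seed = 1)
  expect_setequal(all10$atom_sources, 1:10)
  r1 <- random_dictionary(X, 4, seed = 3)
  expect_identical(r1$atom_sources, random_dictionary(X, 4, seed = 3)$atom_sources)
  expect_false(identical(sort(r1$atom_sources),
                         sort(random_dictionary(X, 4, seed = 4)$atom_sources)) &&
                 identical(r1$atom_sources,
                           random_dictionary(X, 4, seed = 4)$atom_sources))
  expect_equal(length(unique(r1$atom_sources)), 4L)
})

test_that("tidy and glance summarise a selection fit", {
  fx <- make_prototype_corpus(55, K = 3L, d = 10L, reps = 5L)
  sel <- solve_selection(fx$X, auto_lambda(fx$X), max_iter = 2000, tol = 1e-8)
  td <- tidy(sel)
  expect_equal(nrow(td), 15L)
  expect_equal(td$weight[order(td$selected_rank)], sort(td$weight, decreasing = TRUE))
  gl <- glance(sel)
  expect_equal(gl$n_columns, 15L)
  expect_equal(gl$nonzero_rows, sum(sel$weights > 0))
})
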