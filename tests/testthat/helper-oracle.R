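# Independent oracle for the l2,1-regularized self-representation problem:
# ADMM with exact closed-form subproblems (eigendecomposition-based ridge
# solve + its own row shrinkage). Shares no code path with the package's
# accelerated proximal-gradient solver.
oracle_selection_objective <- function(X, B, lambda) {
  0.5 * sum((X - X %*% B)^2) + lambda * sum(sqrt(rowSums(B^2)))
}

oracle_solve_selection <- function(X, lambda, iters = 50000L, tol = 1e-13) {
  N <- ncol(X)
  A <- crossprod(X)
  rho <- max(mean(diag(A)), 1e-3)
  eig <- eigen(A, symmetric = TRUE)
  Q <- eig$vectors
  ev <- pmax(eig$values, 0)
  shrink_rows <- function(M, tau) {
    nrm <- sqrt(rowSums(M^2))
    scl <- ifelse(nrm > tau, 1 - tau / nrm, 0)
    M * scl
  }
  C <- matrix(0, N, N)
  U <- C
  f_old <- Inf
  for (it in seq_len(iters)) {
    B <- Q %*% (crossprod(Q, A + rho * (C - U)) / (ev + rho))
    Cn <- shrink_rows(B + U, lambda / rho)
    U <- U + B - Cn
    if (it %% 50L == 0L) {
      f <- oracle_selection_objective(X, Cn, lambda)
      if (abs(f_old - f) < tol * (1 + abs(f)) && max(abs(B - Cn)) < 1e-10) break
      f_old <- f
    }
    C <- Cn
  }
  list(B = Cn, objective = oracle_selection_objective(X, Cn, lambda))
}

# planted-prototype corpus: K prototypes in [0,1]^d, each repeated `reps`
# times with N(0, noise_sd) perturbation
make_prototype_corpus <- function(seed, K = 5L, d = 100L, reps = 20L,
                                  noise_sd = 0.02) {
  withr::with_seed(seed, {
    protos <- matrix(runif(d * K), d, K)
    X <- protos[, rep(seq_len(K), each = reps)] +
      matrix(rnorm(d * K * reps, 0, noise_sd), d, K * reps)
    list(X = X, protos = protos, group = rep(seq_len(K), each = reps))
  })
}

# nearest planted prototype of each dictionary atom
atom_prototype_map <- function(dict, protos) {
  d2 <- outer(colSums(dict$V^2), colSums(protos^2), `+`) -
    2 * crossprod(dict$V, protos)
  max.col(-d2, ties.method = "first")
}
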