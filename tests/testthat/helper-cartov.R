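# Shared fixtures and independent oracles for the test suite.

truth <- default_truth_params()

# Small PSO configuration for test-scale fits. The package defaults
# (swarm 50, 300 iterations) are for production fits; the synthetic
# problems here are smooth and low-dimensional, and converge well below
# these budgets.
test_pso <- function(seed = 1L, swarm = 24, iters = 150, patience = 25) {
  pso_config(swarm_size = swarm, max_iters = iters, seed = seed,
             patience = patience)
}

rel_err <- function(est, true) abs(est - true) / abs(true)

# Brute-force equilibria oracle: dense grid evaluation of the scaled RHS
# followed by local refinement of candidate roots by minimizing |rhs|^2,
# then de-duplication. Independent of the analytic equilibria lists.
oracle_equilibria <- function(rhs, lower, upper, n_grid = 12, tol = 1e-10) {
  d <- length(lower)
  axes <- lapply(seq_len(d), function(i) {
    seq(lower[i], upper[i], length.out = n_grid)
  })
  grid <- as.matrix(do.call(expand.grid, axes))
  norm2 <- function(x) sum(rhs(x)^2)
  vals <- apply(grid, 1L, norm2)
  cand <- grid[order(vals)[seq_len(min(60L, nrow(grid)))], , drop = FALSE]
  roots <- list()
  for (i in seq_len(nrow(cand))) {
    res <- optim(cand[i, ], norm2, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-16))
    # polish with a second pass
    res <- optim(res$par, norm2, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-16))
    x <- res$par
    if (res$value < tol && all(x > lower - 1e-6) && all(x < upper + 1e-6)) {
      dup <- any(vapply(roots, function(r) max(abs(r - x)) < 1e-4,
                        logical(1)))
      if (!dup) roots[[length(roots) + 1L]] <- x
    }
  }
  roots
}

scaled_cart_rhs <- function(A, B) {
  function(y) c(y[1] * (1 - y[1]) - y[1] * y[2],
                -A * y[2] + B * y[1] * y[2])
}

scaled_ov_rhs <- function(D, E, F) {
  function(y) c(y[1] * (1 - y[1] - y[2]) - y[1] * y[3],
                y[1] * y[3] - D * y[2],
                E * y[2] - F * y[3])
}

# Match an analytic equilibria table against oracle roots: every analytic
# point must be found by the oracle (to tol) and vice versa.
expect_equilibria_match <- function(analytic, roots, tol = 1e-6) {
  pts <- as.matrix(analytic[, seq_len(ncol(analytic) - 1L)])
  expect_equal(nrow(pts), length(roots),
               info = "equilibria count differs from brute-force oracle")
  for (i in seq_len(nrow(pts))) {
    dists <- vapply(roots, function(r) max(abs(r - pts[i, ])), numeric(1))
    expect_lt(min(dists), tol)
  }
}
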