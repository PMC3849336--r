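# Subnetwork objective, exact solver, spectral relaxation and ranking.

test_that("subnetwork_objective sums node weights plus lambda-scaled internal edges", {
  nw <- make_network(c(1, 2, 5), {
    e <- matrix(0, 3, 3); e[1, 2] <- e[2, 1] <- 4; e
  }, lambda = 0.5)
  expect_identical(subnetwork_objective(integer(0), nw), 0)
  expect_identical(subnetwork_objective(1L, nw), 1)
  expect_identical(subnetwork_objective(c(1L, 2L), nw), 1 + 2 + 0.5 * 4)
})

test_that("solve_exact agrees with an independent brute-force enumeration", {
  set.seed(31)
  for (k in 1:20) {
    nw <- random_network(8, lambda = runif(1))
    sol <- solve_exact(nw, K = 3)
    oracle <- oracle_best_subset(as.numeric(nw$node_weights),
                                 nw$edge_weights, nw$lambda, K = 3)
    expect_equal(sol$objective, oracle$objective, tolerance = 1e-12)
    expect_identical(sol$subset, as.integer(oracle$subset))
  }
})

test_that("solve_exact handles degenerate and monotone cases", {
  zero <- make_network(numeric(5), matrix(0, 5, 5))
  sol <- solve_exact(zero, K = 3)
  expect_identical(sol$subset, integer(0))
  expect_identical(sol$objective, 0)

  set.seed(32)
  nw <- random_network(6)
  # nonnegative weights make the objective monotone under inclusion
  expect_identical(solve_exact(nw, K = 6)$subset, 1:6)

  big <- random_network(26)
  expect_error(solve_exact(big, K = 2), class = "synet_complexity_guard_error")
})

test_that("leading_eigenpair matches closed forms and the residual bound", {
  e <- leading_eigenpair(matrix(c(2, 0, 0, 1), 2, 2))
  expect_equal(e$eigenvalue, 2)
  expect_equal(abs(e$eigenvector), c(1, 0))

  e <- leading_eigenpair(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(e$eigenvalue, 1)
  expect_equal(abs(e$eigenvector), c(1, 1) / sqrt(2))

  # [[1,2],[2,3]]: eigenvalues 2 +/- sqrt(5); eigenvector from the 2x2
  # closed form (M - alpha I) x = 0
  M <- matrix(c(1, 2, 2, 3), 2, 2)
  e <- leading_eigenpair(M)
  expect_equal(e$eigenvalue, 2 + sqrt(5), tolerance = 1e-9)
  v <- c(2, (2 + sqrt(5)) - 1)
  v <- v / sqrt(sum(v^2))
  expect_equal(abs(e$eigenvector), v, tolerance = 1e-9)

  set.seed(33)
  for (n in c(5, 50, 200)) {
    A <- matrix(runif(n * n), n, n)
    A <- (A + t(A)) / 2
    e <- leading_eigenpair(A)
    expect_lte(sqrt(sum((A %*% e$eigenvector - e$eigenvalue * e$eigenvector)^2)),
               1e-8 * norm(A, "F"))
    expect_equal(sum(e$eigenvector^2), 1, tolerance = 1e-9)
    # Rayleigh bound with a coordinate vector
    expect_gte(e$eigenvalue, max(diag(A)) - 1e-10)
  }

  expect_error(leading_eigenpair(matrix(c(1, NA, NA, 1), 2, 2)),
               class = "synet_input_error")
})

test_that("a dominant synergistic pair rises to the top of the ranking", {
  set.seed(34)
  n <- 15
  edge <- matrix(0, n, n)
  edge[upper.tri(edge)] <- runif(n * (n - 1) / 2, 0, 0.05)
  edge <- edge + t(edge)
  edge[7, 12] <- edge[12, 7] <- 5  # strong synergy, near-zero node weights
  nw <- make_network(runif(n, 0, 0.05), edge)
  rk <- rank_features(nw)
  expect_setequal(rk$order[1:2], c(7L, 12L))
  # scores agree with a dense eigendecomposition done directly
  ev <- eigen(to_matrix(nw)$M, symmetric = TRUE)
  expect_equal(unname(rk$scores), abs(ev$vectors[, 1]), tolerance = 1e-12)
  expect_equal(sum(rk$scores^2), 1, tolerance = 1e-9)
})

test_that("diagonal fallback reduces to the individual-power ordering", {
  set.seed(35)
  nw <- random_network(6, lambda = 0)
  rk <- rank_features(nw)
  expect_true(rk$diagonal_fallback_used)
  expect_identical(rk$order, order(-as.numeric(nw$node_weights), 1:6))

  zero_edges <- make_network(runif(5), matrix(0, 5, 5), lambda = 1)
  expect_true(rank_features(zero_edges)$diagonal_fallback_used)
})

test_that("uniform matrix ties fall back to node weight then index", {
  ones <- matrix(1, 4, 4); diag(ones) <- 0
  nw <- make_network(rep(1, 4), ones)   # M is all-ones
  rk <- rank_features(nw)
  expect_equal(max(rk$scores) - min(rk$scores), 0, tolerance = 1e-12)
  expect_identical(rk$order, 1:4)

  # tied node weights on the fallback path break by feature index
  nw2 <- make_network(c(1, 3, 3, 2), matrix(0, 4, 4), lambda = 0)
  expect_identical(rank_features(nw2)$order, c(2L, 3L, 4L, 1L))
})

test_that("scale equivariance: c*M scales the eigenvalue, not the order", {
  set.seed(36)
  nw <- random_network(8)
  rk1 <- rank_features(nw)
  nw2 <- nw
  nw2$node_weights <- 3 * nw$node_weights
  nw2$edge_weights <- 3 * nw$edge_weights
  rk2 <- rank_features(nw2)
  expect_equal(rk2$eigenvalue, 3 * rk1$eigenvalue, tolerance = 1e-9)
  expect_identical(rk2$order, rk1$order)
  expect_equal(rk2$scores, rk1$scores, tolerance = 1e-9)
  # Perron: entrywise-positive M gives strictly positive scores
  expect_true(all(rk1$scores > 0))
})

test_that("spectral_topk is dominated by the exact solver", {
  set.seed(37)
  ratios <- numeric(0)
  for (k in 1:25) {
    nw <- random_network(8)
    rk <- rank_features(nw)
    for (K in 2:4) {
      sp <- spectral_topk(rk, K, nw)
      ex <- solve_exact(nw, K)
      expect_lte(sp$objective, ex$objective + 1e-12)
      if (K == 3) ratios <- c(ratios, sp$objective / ex$objective)
    }
  }
  expect_gte(mean(ratios), 0.8)

  nw <- random_network(5)
  rk <- rank_features(nw)
  full <- spectral_topk(rk, 5, nw)
  expect_equal(full$objective,
               sum(nw$node_weights) + sum(nw$edge_weights[upper.tri(nw$edge_weights)]),
               tolerance = 1e-12)
  expect_error(spectral_topk(rk, 0, nw), class = "synet_input_error")
})
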