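# Independent oracles and fixture builders, deliberately coded without
# touching the package's own fitting/eigen/selection routines.

# Newton-Raphson logistic fit with Wald p-values (reference for the IRLS
# core; convergence tightened well past glm's default).
oracle_logit <- function(X, y, tol = 1e-14, maxit = 200) {
  b <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    step <- solve(crossprod(X * W, X), crossprod(X, y - mu))
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% b)
  mu <- 1 / (1 + exp(-eta))
  H <- crossprod(X * (mu * (1 - mu)), X)
  se <- sqrt(diag(solve(H)))
  list(coef = b, se = se, p = 2 * pnorm(-abs(b / se)))
}

# Brute-force maximum-weighted-subnetwork search by explicit double loop
# (independent of subnetwork_objective / solve_exact).
oracle_best_subset <- function(node_w, edge_w, lambda, K) {
  n <- length(node_w)
  best <- list(subset = integer(0), objective = 0)
  for (k in seq_len(K)) {
    cmb <- combn(n, k)
    for (ci in seq_len(ncol(cmb))) {
      s <- cmb[, ci]
      obj <- sum(node_w[s])
      if (k > 1) {
        for (a in seq_len(k - 1)) {
          for (b in seq.int(a + 1, k)) {
            obj <- obj + lambda * edge_w[s[a], s[b]]
          }
        }
      }
      if (obj > best$objective) best <- list(subset = s, objective = obj)
    }
  }
  best
}

# Build a synergy_network object directly from weights (bypasses model
# fitting; used to test the graph algorithms in isolation).
make_network <- function(node_w, edge_w, lambda = 1) {
  n <- length(node_w)
  stopifnot(isSymmetric(edge_w), all(diag(edge_w) == 0))
  nm <- sprintf("f%02d", seq_len(n))
  structure(list(node_weights = setNames(as.numeric(node_w), nm),
                 edge_weights = `dimnames<-`(edge_w, list(nm, nm)),
                 node_pvalues = NULL, edge_pvalues = NULL,
                 lambda = lambda, feature_names = nm, n_failed = 0L),
            class = "synergy_network")
}

random_network <- function(n, lambda = 1) {
  node_w <- runif(n, 0, 3)
  edge_w <- matrix(0, n, n)
  edge_w[upper.tri(edge_w)] <- runif(n * (n - 1) / 2, 0, 3)
  edge_w <- edge_w + t(edge_w)
  make_network(node_w, edge_w, lambda)
}

# Case-control dataset with outcome independent of all features.
null_dataset <- function(n = 100, p = 5) {
  case_control_dataset(matrix(rnorm(n * p), n, p),
                       rep_len(c(0L, 1L), n))
}
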