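#' Subnetwork objective value
#'
#' The weight of a candidate subnetwork \eqn{C}: the sum of its node weights
#' plus \eqn{\lambda} times the sum of the edge weights over unordered pairs
#' inside it,
#' \eqn{\sum_{v_i \in C} f(v_i) + \lambda \sum_{v_i,v_j \in C} s(v_i,v_j)}.
#'
#' @param subset integer vector of feature indices (may be empty).
#' @param network a `synergy_network`.
#' @return the objective value (0 for the empty set).
#' @export
subnetwork_objective <- function(subset, network) {
  subset <- as.integer(subset)
  if (length(subset) == 0L) return(0)
  val <- sum(network$node_weights[subset])
  if (length(subset) > 1L) {
    sub <- network$edge_weights[subset, subset, drop = FALSE]
    val <- val + network$lambda * sum(sub[upper.tri(sub)])
  }
  val
}

#' Exact maximum-weighted-subnetwork search
#'
#' Enumerates every subset of at most `K` features and returns the one
#' maximizing [subnetwork_objective()] -- the exact solution of the
#' size-constrained maximum weighted clique problem.  The problem is
#' NP-hard, so instances above 25 features are refused; use the spectral
#' ranking instead.
#'
#' @param network a `synergy_network` with at most 25 features.
#' @param K maximum subset size (positive integer).
#' @return an object of class `subnetwork_solution` with `subset` (sorted
#'   indices), `objective`, and `K`.  Ties favour the smaller subset, then
#'   lexicographically smaller indices.
#' @export
solve_exact <- function(network, K) {
  n <- length(network$feature_names)
  if (n > 25L) {
    synet_error("synet_complexity_guard_error",
                sprintf("exact search on %d features is infeasible (limit 25); use rank_features()", n))
  }
  K <- as.integer(K)
  if (K < 1L) synet_error("synet_input_error", "K must be a positive integer")

  best_subset <- integer(0)
  best_obj <- 0
  for (k in seq_len(min(K, n))) {
    cmb <- utils::combn(n, k)
    for (c_idx in seq_len(ncol(cmb))) {
      s <- cmb[, c_idx]
      obj <- subnetwork_objective(s, network)
      # strict improvement keeps the first (smallest, lexicographic) optimum
      if (obj > best_obj) {
        best_obj <- obj
        best_subset <- s
      }
    }
  }
  structure(list(subset = best_subset, objective = best_obj, K = K),
            class = "subnetwork_solution")
}

#' Leading eigenpair of a synergy matrix
#'
#' The spectral relaxation of the subnetwork objective: relaxing the binary
#' selection vector to a real unit vector turns the quadratic program
#' \eqn{\max_x x^T M x} subject to \eqn{x^T x \le K} into an eigenproblem
#' \eqn{M x^* = \alpha x^*}, maximized by the algebraically largest
#' eigenvalue.
#'
#' @param M a `synergy_matrix` or plain symmetric numeric matrix.
#' @return list with `eigenvalue` (largest) and `eigenvector` (unit norm).
#' @export
leading_eigenpair <- function(M) {
  if (inherits(M, "synergy_matrix")) M <- M$M
  if (!is.matrix(M) || any(!is.finite(M))) {
    synet_error("synet_input_error", "M must be a finite numeric matrix")
  }
  e <- eigen(M, symmetric = TRUE)
  list(eigenvalue = e$values[1L], eigenvector = e$vectors[, 1L])
}

#' Network-based spectral feature ranking
#'
#' Ranks features by the absolute entries of the leading eigenvector of the
#' synergy matrix, so a feature scores highly if it carries individual
#' power, strong synergies, or sits in a block of mutually synergistic
#' features.  Order is descending by score with a deterministic tie-break
#' (node weight descending, then feature index).  When \eqn{\lambda = 0} or
#' all edge weights vanish, \eqn{M} is diagonal and its leading eigenvector
#' is a coordinate vector that ranks a single feature; the ranking then
#' falls back to the individual-power ordering
#' (`diagonal_fallback_used = TRUE`).
#'
#' @param network a `synergy_network`.
#' @return an object of class `spectral_ranking`: `scores` (named, `|x*_i|`,
#'   unit sum of squares unless the fallback was used), `eigenvalue`,
#'   `order` (feature indices, best first), `node_weights`,
#'   `diagonal_fallback_used`, `unstable` (TRUE if the top two eigenvalues
#'   are within `1e-10 * ||M||_F`), and `feature_names`.
#' @export
rank_features <- function(network) {
  n <- length(network$feature_names)
  nw <- as.numeric(network$node_weights)
  fallback <- network$lambda == 0 || all(network$edge_weights == 0)

  if (fallback) {
    scores <- nw
    eigenvalue <- max(nw)
    unstable <- FALSE
  } else {
    M <- to_matrix(network)$M
    e <- eigen(M, symmetric = TRUE)
    scores <- abs(e$vectors[, 1L])
    eigenvalue <- e$values[1L]
    gap <- e$values[1L] - e$values[2L]
    unstable <- gap < 1e-10 * norm(M, "F")
  }
  # round away eigen-solver noise (~1e-16) so exact score ties (e.g. a
  # uniform Perron vector) fall through to the documented tie-break
  ord <- order(-round(scores, 12), -nw, seq_len(n))
  structure(list(scores = stats::setNames(scores, network$feature_names),
                 eigenvalue = eigenvalue,
                 order = ord,
                 node_weights = stats::setNames(nw, network$feature_names),
                 diagonal_fallback_used = fallback,
                 unstable = unstable,
                 feature_names = network$feature_names,
                 method = "network"),
            class = c("spectral_ranking", "feature_ranking"))
}

#' @export
print.spectral_ranking <- function(x, ...) {
  cat(sprintf("spectral_ranking: %d features, leading eigenvalue %.4f%s%s\n",
              length(x$scores), x$eigenvalue,
              if (x$diagonal_fallback_used) " [diagonal fallback]" else "",
              if (isTRUE(x$unstable)) " [near-degenerate spectrum]" else ""))
  top <- x$order[seq_len(min(5L, length(x$order)))]
  cat("  top:", paste(sprintf("%s (%.3f)", x$feature_names[top],
                              x$scores[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Top-K subnetwork from a spectral ranking
#'
#' The spectral approximation to the exact search: take the `K`
#' highest-scoring features and report their subnetwork objective.
#'
#' @param ranking a `spectral_ranking` (or any `feature_ranking`).
#' @param K subset size, `1 <= K <= n`.
#' @param network the `synergy_network` the ranking was computed from.
#' @return a `subnetwork_solution` (subset sorted ascending).
#' @export
spectral_topk <- function(ranking, K, network) {
  n <- length(ranking$order)
  K <- as.integer(K)
  if (K < 1L || K > n) {
    synet_error("synet_input_error", "K must be between 1 and the number of features")
  }
  s <- sort(ranking$order[seq_len(K)])
  structure(list(subset = s, objective = subnetwork_objective(s, network),
                 K = K),
            class = "subnetwork_solution")
}
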