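#' Build the synergy network of a case-control dataset
#'
#' Computes the node weight \eqn{f(v_i) = -\log p_i} for every feature
#' ([individual_power()]) and the edge weight \eqn{s(v_i,v_j) = -\log p_{ij}}
#' for every one of the \eqn{n(n-1)/2} unordered feature pairs
#' ([pairwise_synergy()]), yielding the weighted graph \eqn{G(V, E)} used by
#' the spectral ranking.  Individual fit failures degrade to zero weight
#' with a single summary warning; only an invalid dataset is an error.
#'
#' @param dataset a [case_control_dataset()].
#' @param lambda weighting coefficient between individual and synergistic
#'   effects, in `[0, 1]`; default 1 weighs them equally.
#' @inheritParams individual_power
#' @return an object of class `synergy_network`: `node_weights` (named
#'   vector), `edge_weights` (symmetric matrix, zero diagonal),
#'   `node_pvalues`, `edge_pvalues`, `lambda`, `feature_names`, and
#'   `n_failed` (count of degraded fits).
#' @export
build_network <- function(dataset, lambda = 1, p_floor = P_FLOOR_DEFAULT,
                          test = c("wald", "lrt")) {
  test <- match.arg(test)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1) {
    synet_error("synet_input_error", "lambda must be a single value in [0, 1]")
  }
  n <- length(dataset$feature_names)
  node_w <- numeric(n)
  node_p <- numeric(n)
  edge_w <- matrix(0, n, n, dimnames = list(dataset$feature_names,
                                            dataset$feature_names))
  edge_p <- matrix(1, n, n)
  diag(edge_p) <- NA_real_
  n_failed <- 0L

  for (i in seq_len(n)) {
    r <- suppressWarnings(individual_power(dataset, i, p_floor, test))
    node_w[i] <- r$weight
    node_p[i] <- r$p_value
    if (r$flag == "failed") n_failed <- n_failed + 1L
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      r <- suppressWarnings(pairwise_synergy(dataset, i, j, p_floor, test))
      edge_w[i, j] <- edge_w[j, i] <- r$weight
      edge_p[i, j] <- edge_p[j, i] <- r$p_value
      if (r$flag == "failed") n_failed <- n_failed + 1L
    }
  }
  if (n_failed > 0L) {
    warning(sprintf("%d logistic fit(s) failed; affected weights set to 0",
                    n_failed), call. = FALSE)
  }
  structure(list(node_weights = stats::setNames(node_w, dataset$feature_names),
                 edge_weights = edge_w,
                 node_pvalues = stats::setNames(node_p, dataset$feature_names),
                 edge_pvalues = edge_p,
                 lambda = lambda,
                 feature_names = dataset$feature_names,
                 n_failed = n_failed),
            class = "synergy_network")
}

#' @export
print.synergy_network <- function(x, ...) {
  n <- length(x$feature_names)
  cat(sprintf("synergy_network: %d nodes, %d edges, lambda = %g\n",
              n, n * (n - 1L) / 2L, x$lambda))
  cat(sprintf("  node weights: max %.3f ('%s'); edge weights: max %.3f\n",
              max(x$node_weights),
              x$feature_names[which.max(x$node_weights)],
              max(x$edge_weights)))
  invisible(x)
}

#' Synergy matrix of a network
#'
#' The symmetric matrix \eqn{M} whose diagonal holds the individual powers,
#' \eqn{M_{ii} = f(v_i)}, and whose off-diagonal entries are the scaled
#' synergistic powers, \eqn{M_{ij} = \lambda\, s(v_i, v_j)}.  Its leading
#' eigenvector drives the spectral feature ranking.
#'
#' @param network a `synergy_network`.
#' @return an object of class `synergy_matrix` with elements `M` and
#'   `feature_names`.
#' @export
to_matrix <- function(network) {
  M <- network$lambda * network$edge_weights
  diag(M) <- network$node_weights
  structure(list(M = M, feature_names = network$feature_names),
            class = "synergy_matrix")
}

#' Element-wise average of synergy networks
#'
#' Averages node and edge weights across networks built on resampled data
#' (e.g. the training portions of repeated cross-validation), producing the
#' consensus "average synergy network".  All networks must share feature
#' names and lambda.
#'
#' @param networks non-empty list of `synergy_network` objects.
#' @return a `synergy_network` with averaged weights (p-values are dropped).
#' @export
average_networks <- function(networks) {
  if (length(networks) == 0L) {
    synet_error("synet_input_error", "need at least one network")
  }
  ref <- networks[[1L]]
  for (nw in networks[-1L]) {
    if (!identical(nw$feature_names, ref$feature_names) ||
        !identical(nw$lambda, ref$lambda)) {
      synet_error("synet_input_error",
                  "networks differ in feature names or lambda")
    }
  }
  node_w <- Reduce(`+`, lapply(networks, `[[`, "node_weights")) / length(networks)
  edge_w <- Reduce(`+`, lapply(networks, `[[`, "edge_weights")) / length(networks)
  structure(list(node_weights = node_w, edge_weights = edge_w,
                 node_pvalues = NULL, edge_pvalues = NULL,
                 lambda = ref$lambda, feature_names = ref$feature_names,
                 n_failed = sum(vapply(networks, `[[`, integer(1), "n_failed"))),
            class = "synergy_network")
}
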