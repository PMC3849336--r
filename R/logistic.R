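#' @noRd
P_FLOOR_DEFAULT <- 1e-300
RIDGE_FALLBACK <- 1e-4

# Fit a binomial-logit GLM by IRLS (compiled) and return the two-sided Wald
# p-value of the coefficient in position `term`, with a likelihood-ratio
# alternative behind `test = "lrt"`.  Handles the failure ladder:
#   * complete separation -> p capped at p_floor (the term is "infinitely"
#     significant; the cap keeps the -log p weight finite),
#   * non-convergence -> refit with a small ridge (1e-4) on the slopes,
#   * still failing, or a rank-deficient design (e.g. a collinear product
#     term) -> p = 1, weight 0, with a warning flag.
#' @noRd
logit_term_pvalue <- function(X, y, term, p_floor = P_FLOOR_DEFAULT,
                              test = c("wald", "lrt")) {
  test <- match.arg(test)
  fit <- logit_irls(X, y)
  flag <- "ok"

  if (fit$separated) {
    return(list(p_value = p_floor, flag = "separation"))
  }
  if (!fit$ok || !fit$converged) {
    # a rank-deficient design (e.g. collinear product term) cannot support
    # a Wald test for the term; ridge would only mask the deficiency
    if (qr(X)$rank < ncol(X)) {
      return(list(p_value = 1, flag = "failed"))
    }
    fit <- logit_irls(X, y, ridge = RIDGE_FALLBACK)
    flag <- "ridge"
    if (fit$separated) {
      return(list(p_value = p_floor, flag = "separation"))
    }
    if (!fit$ok || !fit$converged) {
      return(list(p_value = 1, flag = "failed"))
    }
  }

  if (test == "wald") {
    se <- fit$se[term]
    if (!is.finite(se) || se <= 0) {
      return(list(p_value = 1, flag = "failed"))
    }
    z <- fit$coefficients[term] / se
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    red <- logit_irls(X[, -term, drop = FALSE], y)
    if (!red$ok) {
      return(list(p_value = 1, flag = "failed"))
    }
    lr <- red$deviance - fit$deviance
    p <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  }
  list(p_value = max(min(p, 1), p_floor), flag = flag)
}

#' Individual predictive power of one feature
#'
#' Fits the single-variable logistic model
#' \eqn{\log(g/(1-g)) = \alpha_0 + \alpha_1 v_i} and converts the coefficient
#' p-value of \eqn{\alpha_1} into the node weight \eqn{f(v_i) = -\log p_i}.
#' The p-value is the two-sided Wald test by default; `test = "lrt"` uses a
#' likelihood-ratio test instead.  p-values are capped below at `p_floor` so
#' weights stay finite under separation or underflow.
#'
#' @param dataset a [case_control_dataset()].
#' @param i feature index.
#' @param p_floor lower cap on the p-value (default `1e-300`).
#' @param test `"wald"` (default) or `"lrt"`.
#' @return list with `weight` (`-log` of the capped p-value), `p_value`, and
#'   `flag` (`"ok"`, `"separation"`, `"ridge"`, or `"failed"`; a failed fit
#'   yields weight 0).
#' @export
individual_power <- function(dataset, i, p_floor = P_FLOOR_DEFAULT,
                             test = c("wald", "lrt")) {
  v <- dataset$features[, i]
  if (stats::var(v) == 0) {
    synet_error("synet_degenerate_feature_error",
                sprintf("feature %d ('%s') is constant", i,
                        dataset$feature_names[i]))
  }
  res <- logit_term_pvalue(cbind(1, v), as.numeric(dataset$outcome), 2L,
                           p_floor, test)
  if (res$flag == "failed") {
    warning(sprintf("logistic fit for feature %d failed; weight set to 0", i),
            call. = FALSE)
  }
  list(weight = -log(res$p_value), p_value = res$p_value, flag = res$flag)
}

#' Pairwise synergistic power of two features
#'
#' Fits \eqn{\log(g/(1-g)) = \alpha_0 + \alpha_1 v_i + \alpha_2 v_j +
#' \beta v_i v_j} and converts the coefficient p-value of the interaction
#' term \eqn{\beta} (main-effect p-values are discarded) into the edge
#' weight \eqn{s(v_i, v_j) = -\log p_{ij}}.  The pair is canonicalized to
#' `(min(i,j), max(i,j))` so the result is bit-for-bit symmetric in its
#' arguments.
#'
#' @inheritParams individual_power
#' @param j second feature index (`j != i`).
#' @return list with `weight`, `p_value` and `flag` as in
#'   [individual_power()]; a collinear product term yields weight 0 with
#'   flag `"failed"`.
#' @export
pairwise_synergy <- function(dataset, i, j, p_floor = P_FLOOR_DEFAULT,
                             test = c("wald", "lrt")) {
  if (i == j) {
    synet_error("synet_input_error", "pairwise synergy needs two distinct features")
  }
  a <- min(i, j); b <- max(i, j)
  vi <- dataset$features[, a]
  vj <- dataset$features[, b]
  if (stats::var(vi) == 0 || stats::var(vj) == 0) {
    synet_error("synet_degenerate_feature_error",
                sprintf("constant feature in pair (%d, %d)", a, b))
  }
  res <- logit_term_pvalue(cbind(1, vi, vj, vi * vj),
                           as.numeric(dataset$outcome), 4L, p_floor, test)
  if (res$flag == "failed") {
    warning(sprintf("interaction fit for pair (%d, %d) failed; weight set to 0",
                    a, b), call. = FALSE)
  }
  list(weight = -log(res$p_value), p_value = res$p_value, flag = res$flag)
}
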