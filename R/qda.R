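QDA_REG_DEFAULT <- 1e-4
# Shrinkage escalation ladder; must stay in sync with src/qda_cv.cpp.
QDA_REG_LADDER <- c(1e-2, 1e-1, 0.5)

#' @noRd
shrunk_chol <- function(S, reg) {
  d <- nrow(S)
  tr <- sum(diag(S))
  scale <- if (tr > 0) tr / d else 1e-8
  for (g in c(reg, QDA_REG_LADDER[QDA_REG_LADDER >= reg])) {
    Sr <- (1 - g) * S
    diag(Sr) <- diag(Sr) + g * scale
    R <- tryCatch(chol(Sr), error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  NULL
}

#' Fit a quadratic discriminant analysis classifier
#'
#' Gaussian class-conditional model with class-specific covariance matrices,
#' so quadratic decision boundaries can exploit pairwise feature
#' interactions.  Priors are the class frequencies; covariances are the
#' per-class sample covariances shrunk toward `(trace/d) * I` with
#' coefficient `reg` (escalated automatically if the Cholesky factorization
#' fails, e.g. for near-singular covariances on small folds).
#'
#' @param train_features numeric matrix (samples x d).
#' @param train_outcome binary 0/1 vector; each class needs at least 2
#'   samples.
#' @param reg shrinkage coefficient (default `1e-4`).
#' @return an object of class `qda_model`.
#' @export
fit_qda <- function(train_features, train_outcome, reg = QDA_REG_DEFAULT) {
  X <- as.matrix(train_features)
  y <- as.integer(train_outcome)
  classes <- list()
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    if (length(idx) < 2L) {
      synet_error("synet_insufficient_class_error",
                  sprintf("class %d has %d sample(s); need at least 2",
                          cls, length(idx)))
    }
    Xc <- X[idx, , drop = FALSE]
    S <- stats::cov(Xc)
    R <- shrunk_chol(S, reg)
    if (is.null(R)) {
      synet_error("synet_input_error",
                  sprintf("covariance of class %d cannot be factorized", cls))
    }
    classes[[as.character(cls)]] <- list(
      prior = length(idx) / length(y),
      mean = colMeans(Xc),
      chol = R,
      logdet = 2 * sum(log(diag(R))))
  }
  structure(list(classes = classes, d = ncol(X), reg = reg),
            class = "qda_model")
}

#' @noRd
qda_class_logdens <- function(cls, X) {
  Xc <- sweep(X, 2L, cls$mean)
  Z <- backsolve(cls$chol, t(Xc), transpose = TRUE)
  mahal <- colSums(Z^2)
  log(cls$prior) - 0.5 * cls$logdet - 0.5 * mahal
}

#' Posterior case probability under a QDA model
#'
#' \eqn{P(y = 1 \mid v)} per sample, from the class-conditional Gaussian
#' log-densities plus log-priors with a numerically stable normalization.
#'
#' @param model a `qda_model`.
#' @param features numeric matrix with the model's feature dimension.
#' @return numeric vector of posteriors in `[0, 1]`.
#' @export
qda_posterior <- function(model, features) {
  X <- as.matrix(features)
  if (ncol(X) != model$d) {
    synet_error("synet_input_error",
                sprintf("feature dimension %d does not match model dimension %d",
                        ncol(X), model$d))
  }
  l1 <- qda_class_logdens(model$classes[["1"]], X)
  l0 <- qda_class_logdens(model$classes[["0"]], X)
  1 / (1 + exp(l0 - l1))
}

#' Classification accuracy
#'
#' Fraction of agreeing positions; the package's prediction rule thresholds
#' the QDA posterior at 0.5.
#'
#' @param outcome binary 0/1 vector.
#' @param predicted binary 0/1 vector of equal length.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(outcome, predicted) {
  if (length(outcome) == 0L || length(outcome) != length(predicted)) {
    synet_error("synet_input_error", "outcome and predicted must be non-empty and equal length")
  }
  mean(outcome == predicted)
}

#' Area under the ROC curve
#'
#' Mann-Whitney U statistic normalized by \eqn{n_1 n_0}, with ties counted
#' one half -- the probability a random case is scored above a random
#' control, equal to the trapezoidal area under the empirical ROC curve.
#'
#' @param outcome binary 0/1 vector containing both classes.
#' @param scores numeric score vector (higher = more case-like).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(outcome, scores) {
  if (length(outcome) != length(scores)) {
    synet_error("synet_input_error", "outcome and scores must have equal length")
  }
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  if (n1 == 0L || n0 == 0L) {
    synet_error("synet_undefined_metric_error",
                "AUC is undefined when only one class is present")
  }
  r <- rank(scores)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
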