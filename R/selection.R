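#' Individual-power feature ranking (baseline)
#'
#' The traditional filter baseline: features ordered by their individual
#' power \eqn{-\log p_i} alone, ignoring all pairwise synergies.  Uses the
#' same tie-break convention as [rank_features()] (weight descending, then
#' feature index).
#'
#' @inheritParams individual_power
#' @return a `feature_ranking` with `scores` (= node weights), `order`, and
#'   `method = "individual"`.
#' @export
individual_ranking <- function(dataset, p_floor = P_FLOOR_DEFAULT,
                               test = c("wald", "lrt")) {
  n <- length(dataset$feature_names)
  w <- vapply(seq_len(n),
              function(i) individual_power(dataset, i, p_floor, test)$weight,
              numeric(1))
  structure(list(scores = stats::setNames(w, dataset$feature_names),
                 order = order(-w, seq_len(n)),
                 node_weights = stats::setNames(w, dataset$feature_names),
                 feature_names = dataset$feature_names,
                 method = "individual"),
            class = "feature_ranking")
}

# Inner-CV score of a non-empty candidate feature subset: fold-mean of the
# metric plus the count of skipped (undefined) folds.
#' @noRd
inner_cv_score <- function(X, y, subset, folds, k, metric, reg, auc_labels) {
  m <- qda_cv_metrics(X[, subset, drop = FALSE], y, folds, k, reg, auc_labels)
  vals <- m[, if (metric == "accuracy") 1L else 2L]
  list(score = mean(vals, na.rm = TRUE), n_skipped = sum(is.na(vals)))
}

#' Forward feature selection along a ranked list
#'
#' Single pass down `ranked`: starting from the empty set, each candidate is
#' accepted iff adding it strictly improves (by more than `eps`) the inner
#' stratified `inner_folds`-fold cross-validated QDA metric over the current
#' best; rejected candidates are never revisited.  Inner folds are fixed by
#' `seed` so all candidates are scored on identical splits.  The empty set
#' scores 0, so the top-ranked candidate always enters: this matters when no
#' feature carries a marginal effect (purely synergistic signal), where an
#' accuracy-level baseline would block the first member of every interacting
#' pair and the pair could never form.
#'
#' @param ranked a `feature_ranking` or an integer permutation of all
#'   feature indices, best first.
#' @param train a [case_control_dataset()].
#' @param metric `"accuracy"` or `"auc"`.
#' @param inner_folds number of inner CV folds (default 10).
#' @param seed integer seed fixing the inner fold assignment.
#' @param eps strict-improvement margin (default `1e-12`).
#' @param reg QDA covariance shrinkage passed to the classifier.
#' @param auc_from `"labels"` (default) scores AUC from the 0.5-thresholded
#'   predictions -- balanced accuracy, the convention the reference results
#'   follow -- `"posterior"` from the continuous posterior.
#' @param warn emit a warning when inner folds were skipped (single-class
#'   held-out parts in tiny data).
#' @return an object of class `selection_result`: `selected` (indices in
#'   acceptance order), `inner_cv_trace` (one row per candidate: feature,
#'   metric with/without, accepted), `metric_name`, `n_skipped_folds`.
#' @export
forward_select <- function(ranked, train, metric = c("accuracy", "auc"),
                           inner_folds = 10L, seed = 1L, eps = 1e-12,
                           reg = QDA_REG_DEFAULT,
                           auc_from = c("labels", "posterior"), warn = TRUE) {
  metric <- match.arg(metric)
  auc_labels <- match.arg(auc_from) == "labels"
  if (inherits(ranked, "feature_ranking")) ranked <- ranked$order
  ranked <- as.integer(ranked)
  n <- ncol(train$features)
  if (!identical(sort(ranked), seq_len(n))) {
    synet_error("synet_input_error",
                "ranked must be a permutation of all feature indices")
  }
  X <- train$features
  y <- train$outcome
  folds <- stratified_folds(y, inner_folds, seed)

  selected <- integer(0)
  best <- 0   # empty-set score: any positive metric admits the first candidate
  n_skipped <- 0L
  trace <- data.frame(feature = ranked,
                      metric_before = NA_real_, metric_with = NA_real_,
                      accepted = FALSE)
  for (k in seq_along(ranked)) {
    cand <- ranked[k]
    sc <- inner_cv_score(X, y, c(selected, cand), folds, inner_folds,
                         metric, reg, auc_labels)
    n_skipped <- n_skipped + sc$n_skipped
    trace$metric_before[k] <- best
    trace$metric_with[k] <- sc$score
    if (is.finite(sc$score) && sc$score > best + eps) {
      selected <- c(selected, cand)
      best <- sc$score
      trace$accepted[k] <- TRUE
    }
  }
  if (warn && n_skipped > 0L) {
    warning(sprintf("%d inner CV fold evaluation(s) skipped (single-class or degenerate fold)",
                    n_skipped), call. = FALSE)
  }
  structure(list(selected = selected, inner_cv_trace = trace,
                 metric_name = metric, inner_folds = inner_folds,
                 seed = seed, n_skipped_folds = n_skipped),
            class = "selection_result")
}

# Score a trained-on-train, tested-on-test split for a fixed subset;
# empty subsets fall back to the training-majority classifier.
#' @noRd
score_split <- function(X, y, train_idx, test_idx, subset, reg, auc_labels) {
  yte <- y[test_idx]
  if (length(subset) == 0L) {
    maj <- if (mean(y[train_idx]) > 0.5) 1L else 0L
    acc <- mean(yte == maj)
    auc <- if (length(unique(yte)) < 2L) NA_real_ else 0.5
    return(c(accuracy = acc, auc = auc))
  }
  model <- tryCatch(
    fit_qda(X[train_idx, subset, drop = FALSE], y[train_idx], reg),
    synergynet_error = function(e) NULL)
  if (is.null(model)) return(c(accuracy = NA_real_, auc = NA_real_))
  post <- qda_posterior(model, X[test_idx, subset, drop = FALSE])
  pred <- as.integer(post > 0.5)
  acc <- mean(yte == pred)
  auc <- if (length(unique(yte)) < 2L) NA_real_ else
    auc_score(yte, if (auc_labels) as.numeric(pred) else post)
  c(accuracy = acc, auc = auc)
}

#' Embedded cross-validation evaluation
#'
#' The leakage-free protocol for estimating the predictive power of a
#' ranking-plus-selection pipeline.  For each of `n_repeats` repetitions the
#' data are split into `n_folds` stratified outer folds; on each outer
#' training portion (and on it only) the synergy network is rebuilt, features
#' are re-ranked (`"network"` = spectral ranking, `"individual"` = individual
#' power), and forward selection with inner 10-fold CV picks a subset; a QDA
#' classifier refit on the training portion is then scored on the held-out
#' fold.  No held-out sample ever enters network construction, ranking or
#' selection.
#'
#' @param dataset a [case_control_dataset()].
#' @param ranking_method `"network"` or `"individual"`.
#' @param metric `"accuracy"` or `"auc"` -- the criterion optimized during
#'   forward selection (both metrics are always recorded on the held-out
#'   folds).
#' @param lambda synergy-vs-individual weighting for the network ranking.
#' @param n_folds outer folds (default 10).
#' @param n_repeats outer repetitions (default 100; the reference protocol
#'   records `100 x 10 = 1000` selected subsets).
#' @param seed master seed; all fold assignments and inner seeds derive
#'   from it, so identical seeds give bit-identical reports.
#' @param inner_folds inner CV folds for forward selection.
#' @param consensus_threshold selection-frequency threshold of the consensus
#'   biomarker set (default 0.40).
#' @param eps strict-improvement margin of the inner forward selection.
#' @param auc_from AUC convention, `"labels"` (default; reproduces the
#'   reference protocol, where reported AUC tracks accuracy on balanced
#'   data) or `"posterior"` (Mann-Whitney on the continuous posterior).
#' @param reg QDA covariance shrinkage.
#' @param p_floor,test passed to the logistic fits.
#' @param keep_networks store the per-fold synergy networks (network method
#'   only) so [average_networks()] can form the average synergy network.
#' @param .inspect optional callback `function(rep, fold, train_idx,
#'   test_idx)` used by integration tests to audit the fold partition.
#' @return an object of class `evaluation_report`; see
#'   [consensus_biomarkers()] and [write_report()].
#' @export
embedded_cv <- function(dataset, ranking_method = c("network", "individual"),
                        metric = c("accuracy", "auc"), lambda = 1,
                        n_folds = 10L, n_repeats = 100L, seed = 1L,
                        inner_folds = 10L, consensus_threshold = 0.40,
                        eps = 1e-12, reg = QDA_REG_DEFAULT,
                        auc_from = c("labels", "posterior"),
                        p_floor = P_FLOOR_DEFAULT, test = c("wald", "lrt"),
                        keep_networks = FALSE, .inspect = NULL) {
  ranking_method <- match.arg(ranking_method)
  auc_from <- match.arg(auc_from)
  metric <- match.arg(metric)
  test <- match.arg(test)
  n <- ncol(dataset$features)
  X <- dataset$features
  y <- dataset$outcome

  rep_seeds <- derive_seeds(seed, n_repeats)
  records <- vector("list", n_repeats * n_folds)
  subsets <- vector("list", n_repeats * n_folds)
  networks <- if (keep_networks) vector("list", n_repeats * n_folds) else NULL
  n_empty <- 0L
  n_skipped <- 0L

  for (r in seq_len(n_repeats)) {
    s <- derive_seeds(rep_seeds[r], 1L + n_folds)
    folds <- stratified_folds(y, n_folds, s[1L])
    for (f in seq_len(n_folds)) {
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      if (!is.null(.inspect)) .inspect(r, f, train_idx, test_idx)
      train <- dataset_rows(dataset, train_idx)

      if (ranking_method == "network") {
        nw <- suppressWarnings(build_network(train, lambda, p_floor, test))
        ranking <- rank_features(nw)
        if (keep_networks) networks[[(r - 1L) * n_folds + f]] <- nw
      } else {
        ranking <- individual_ranking(train, p_floor, test)
      }
      sel <- forward_select(ranking, train, metric, inner_folds,
                            seed = s[1L + f], eps = eps, reg = reg,
                            auc_from = auc_from, warn = FALSE)
      n_skipped <- n_skipped + sel$n_skipped_folds
      subset <- sel$selected
      if (length(subset) == 0L) n_empty <- n_empty + 1L

      sc <- score_split(X, y, train_idx, test_idx, subset, reg,
                        auc_from == "labels")
      k <- (r - 1L) * n_folds + f
      records[[k]] <- data.frame(rep = r, fold = f,
                                 accuracy = sc[["accuracy"]],
                                 auc = sc[["auc"]],
                                 n_selected = length(subset))
      subsets[[k]] <- subset
    }
  }
  records <- do.call(rbind, records)
  freq <- tabulate(unlist(subsets), nbins = n) / (n_repeats * n_folds)
  freq <- stats::setNames(freq, dataset$feature_names)

  report <- structure(list(
    ranking_method = ranking_method, metric = metric, lambda = lambda,
    n_repeats = n_repeats, n_folds = n_folds, inner_folds = inner_folds,
    seed = as.integer(seed), consensus_threshold = consensus_threshold,
    feature_names = dataset$feature_names,
    records = records, subsets = subsets,
    selection_frequency = freq,
    consensus = which(freq >= consensus_threshold),
    mean_accuracy = mean(records$accuracy, na.rm = TRUE),
    sd_accuracy = stats::sd(records$accuracy, na.rm = TRUE),
    mean_auc = mean(records$auc, na.rm = TRUE),
    sd_auc = stats::sd(records$auc, na.rm = TRUE),
    n_empty_selections = n_empty,
    n_skipped_inner_folds = n_skipped,
    networks = networks),
    class = "evaluation_report")
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %s ranking, %s-guided selection, lambda = %g\n",
              x$ranking_method, x$metric, x$lambda))
  cat(sprintf("  %d repeats x %d folds (%d subsets); mean accuracy %.4f (sd %.4f), mean AUC %.4f (sd %.4f)\n",
              x$n_repeats, x$n_folds, length(x$subsets),
              x$mean_accuracy, x$sd_accuracy, x$mean_auc, x$sd_auc))
  if (length(x$consensus)) {
    cat(sprintf("  consensus (>= %d%%): %s\n", round(100 * x$consensus_threshold),
                paste(x$feature_names[x$consensus], collapse = ", ")))
  } else {
    cat("  consensus: (empty)\n")
  }
  invisible(x)
}

#' Consensus biomarkers from an evaluation report
#'
#' Features whose selection frequency across all `n_repeats x n_folds`
#' selected subsets reaches `threshold` (ties at the threshold are
#' included).
#'
#' @param report an `evaluation_report`.
#' @param threshold frequency threshold in `[0, 1]` (default 0.40).
#' @return sorted integer vector of feature indices (named).
#' @export
consensus_biomarkers <- function(report, threshold = 0.40) {
  idx <- which(report$selection_frequency >= threshold)
  stats::setNames(idx, report$feature_names[idx])
}

# Shared core of evaluate_subset / exhaustive_search: score one subset on a
# fixed list of fold assignments (one per repeat).
#' @noRd
eval_subset_on_folds <- function(X, y, subset, folds_list, n_folds, reg,
                                 auc_labels = TRUE) {
  accs <- numeric(0)
  aucs <- numeric(0)
  for (folds in folds_list) {
    m <- qda_cv_metrics(X[, subset, drop = FALSE], y, folds, n_folds, reg,
                        auc_labels)
    accs <- c(accs, m[, 1L])
    aucs <- c(aucs, m[, 2L])
  }
  list(mean_accuracy = mean(accs, na.rm = TRUE),
       mean_auc = mean(aucs, na.rm = TRUE))
}

#' Repeated cross-validated performance of a fixed feature subset
#'
#' Repeated stratified `n_folds`-fold CV of QDA restricted to `subset`; no
#' selection happens inside, so this is the unbiased score of an already
#' chosen biomarker set (e.g. the consensus set).
#'
#' @inheritParams embedded_cv
#' @param subset non-empty integer vector of feature indices.
#' @return list with `mean_accuracy` and `mean_auc`.
#' @export
evaluate_subset <- function(dataset, subset, n_repeats = 100L, n_folds = 10L,
                            seed = 1L, reg = QDA_REG_DEFAULT,
                            auc_from = c("labels", "posterior")) {
  auc_labels <- match.arg(auc_from) == "labels"
  subset <- as.integer(subset)
  if (length(subset) == 0L) {
    synet_error("synet_input_error", "subset must be non-empty")
  }
  rep_seeds <- derive_seeds(seed, n_repeats)
  folds_list <- lapply(rep_seeds, function(s)
    stratified_folds(dataset$outcome, n_folds, s))
  eval_subset_on_folds(dataset$features, dataset$outcome, subset,
                       folds_list, n_folds, reg, auc_labels)
}

#' Exhaustive search over all feature subsets
#'
#' Scores every non-empty subset by repeated cross-validated QDA (identical
#' folds for every subset, fixed by `seed`) and returns the best one -- the
#' brute-force reference that ranking-based selection is compared against.
#' Exponential in the number of features, hence guarded.
#'
#' @inheritParams evaluate_subset
#' @param metric `"accuracy"` or `"auc"`.
#' @param max_features complexity guard (default 16).
#' @param override set `TRUE` to bypass the guard deliberately.
#' @return list with `subset` (best indices), `score`, `metric`.
#' @export
exhaustive_search <- function(dataset, metric = c("accuracy", "auc"),
                              max_features = 16L, n_repeats = 10L,
                              n_folds = 10L, seed = 1L,
                              reg = QDA_REG_DEFAULT, override = FALSE) {
  metric <- match.arg(metric)
  n <- ncol(dataset$features)
  if (n > max_features && !override) {
    synet_error("synet_complexity_guard_error",
                sprintf("%d features means %s subsets; raise max_features or set override = TRUE",
                        n, format(2^n - 1, big.mark = ",")))
  }
  rep_seeds <- derive_seeds(seed, n_repeats)
  folds_list <- lapply(rep_seeds, function(s)
    stratified_folds(dataset$outcome, n_folds, s))

  key <- if (metric == "accuracy") "mean_accuracy" else "mean_auc"
  best_subset <- NULL
  best_score <- -Inf
  # masks enumerate subsets in size-then-lexicographic-compatible order only
  # approximately; ties are resolved explicitly below
  for (mask in seq_len(2^n - 1)) {
    subset <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    sc <- eval_subset_on_folds(dataset$features, dataset$outcome, subset,
                               folds_list, n_folds, reg)[[key]]
    better <- sc > best_score ||
      (sc == best_score && !is.null(best_subset) &&
         (length(subset) < length(best_subset) ||
            (length(subset) == length(best_subset) &&
               paste(subset, collapse = ",") < paste(best_subset, collapse = ","))))
    if (better) {
      best_score <- sc
      best_subset <- subset
    }
  }
  list(subset = best_subset, score = best_score, metric = metric)
}
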