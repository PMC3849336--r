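# Forward selection, embedded CV, consensus, subset evaluation, exhaustive search.

test_that("individual_ranking sorts by individual power with the shared tie-break", {
  set.seed(51)
  n <- 400
  X <- cbind(rnorm(n), rnorm(n), rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * X[, 2] + 0.5 * X[, 3]))
  d <- case_control_dataset(X, y)
  rk <- individual_ranking(d)
  expect_identical(rk$order, order(-as.numeric(rk$scores), 1:3))
  expect_identical(rk$order[1], 2L)

  # equals rank_features at lambda = 0
  nw <- build_network(d, lambda = 0)
  expect_identical(rank_features(nw)$order, rk$order)
})

test_that("a strong main effect ranks first in nearly all replicates", {
  set.seed(52)
  hits <- 0L
  for (k in 1:100) {
    n <- 150
    X <- matrix(rnorm(n * 4), n, 4)
    y <- rbinom(n, 1, plogis(2 * X[, 3]))
    if (length(unique(y)) < 2) next
    d <- case_control_dataset(X, y)
    if (individual_ranking(d)$order[1] == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("forward selection accepts a perfectly predictive feature", {
  set.seed(53)
  n <- 100
  y <- rep_len(c(0L, 1L), n)
  X <- cbind(y + rnorm(n, sd = 0.05), matrix(rnorm(n * 3), n, 3))
  d <- case_control_dataset(X, y)
  sel <- forward_select(c(1L, 2L, 3L, 4L), d, "accuracy", seed = 5)
  expect_true(1L %in% sel$selected)
  split <- rep(1:2, each = n / 2)
  m <- fit_qda(X[split == 1, sel$selected, drop = FALSE], y[split == 1])
  post <- qda_posterior(m, X[split == 2, sel$selected, drop = FALSE])
  expect_gte(accuracy(y[split == 2], as.integer(post > 0.5)), 0.95)
})

test_that("the accepted prefix has strictly increasing inner-CV metric", {
  set.seed(54)
  cfg <- sim_config(n_features = 10, n_synergy_pairs = 3)
  tr <- draw_ground_truth(cfg, 1)
  d <- simulate_dataset(cfg, tr, 2)
  for (metric in c("accuracy", "auc")) {
    sel <- forward_select(seq_len(10), d, metric, seed = 7, warn = FALSE)
    acc_rows <- sel$inner_cv_trace[sel$inner_cv_trace$accepted, ]
    if (nrow(acc_rows) > 1) {
      expect_true(all(diff(acc_rows$metric_with) > 0))
    }
    expect_false(anyDuplicated(sel$selected) > 0)
    # every acceptance strictly improved on the metric before it
    expect_true(all(acc_rows$metric_with > acc_rows$metric_before))
  }
})

test_that("pure-noise features yield sparse selections", {
  # The strict-improvement rule keeps null selections well below the 30
  # candidates: measured mean ~5 of 30 over replicates (record-chain
  # behaviour of noisy CV estimates; see the methods vignette).
  set.seed(55)
  sizes <- vapply(1:15, function(k) {
    X <- matrix(rnorm(200 * 30), 200, 30)
    y <- rbinom(200, 1, 0.5)
    d <- case_control_dataset(X, y)
    length(forward_select(sample(30), d, "accuracy", seed = k,
                          warn = FALSE)$selected)
  }, numeric(1))
  expect_lt(mean(sizes), 8)
})

test_that("forward_select validates the ranked permutation", {
  d <- null_dataset(40, 4)
  expect_error(forward_select(c(1L, 2L), d, "accuracy", seed = 1),
               class = "synet_input_error")
  expect_error(forward_select(c(1L, 1L, 2L, 3L), d, "accuracy", seed = 1),
               class = "synet_input_error")
})

test_that("embedded_cv records n_repeats x n_folds subsets and is reproducible", {
  set.seed(56)
  cfg <- sim_config(n_features = 6, n_samples = 100, n_synergy_pairs = 2)
  tr <- draw_ground_truth(cfg, 3)
  d <- simulate_dataset(cfg, tr, 4)
  r1 <- embedded_cv(d, "network", "accuracy", n_folds = 10, n_repeats = 2,
                    seed = 11)
  expect_identical(length(r1$subsets), 20L)
  expect_identical(nrow(r1$records), 20L)
  expect_true(all(r1$selection_frequency >= 0 & r1$selection_frequency <= 1))
  r2 <- embedded_cv(d, "network", "accuracy", n_folds = 10, n_repeats = 2,
                    seed = 11)
  expect_identical(r1, r2)
  r3 <- embedded_cv(d, "network", "accuracy", n_folds = 10, n_repeats = 2,
                    seed = 12)
  expect_false(identical(r1$records, r3$records))
})

test_that("outer folds partition the data and never leak into training", {
  set.seed(57)
  cfg <- sim_config(n_features = 4, n_samples = 80, n_synergy_pairs = 1)
  d <- simulate_dataset(cfg, draw_ground_truth(cfg, 5), 6)
  seen <- new.env()
  embedded_cv(d, "individual", "accuracy", n_folds = 5, n_repeats = 2,
              seed = 13, .inspect = function(r, f, train_idx, test_idx) {
                expect_length(intersect(train_idx, test_idx), 0)
                expect_setequal(c(train_idx, test_idx), seq_len(80))
                key <- sprintf("r%d", r)
                seen[[key]] <- c(seen[[key]], test_idx)
              })
  # across the folds of one repeat, every sample is held out exactly once
  for (key in ls(seen)) {
    expect_identical(sort(seen[[key]]), seq_len(80L))
  }
})

test_that("kept per-fold networks average into a consensus network", {
  set.seed(62)
  cfg <- sim_config(n_features = 4, n_samples = 60, n_synergy_pairs = 1)
  d <- simulate_dataset(cfg, draw_ground_truth(cfg, 63), 64)
  r <- embedded_cv(d, "network", "accuracy", n_folds = 5, n_repeats = 1,
                   seed = 65, keep_networks = TRUE)
  expect_length(r$networks, 5L)
  avg <- average_networks(r$networks)
  expect_identical(avg$feature_names, d$feature_names)
  expect_equal(avg$edge_weights,
               Reduce(`+`, lapply(r$networks, `[[`, "edge_weights")) / 5)
})

test_that("consensus_biomarkers applies an inclusive threshold", {
  report <- structure(list(
    selection_frequency = c(a = 0.40, b = 0.39, c = 1.0, d = 0.999, e = 0),
    feature_names = c("a", "b", "c", "d", "e")),
    class = "evaluation_report")
  expect_identical(unname(consensus_biomarkers(report, 0.40)), c(1L, 3L, 4L))
  expect_identical(unname(consensus_biomarkers(report, 0)), 1:5)
  expect_identical(unname(consensus_biomarkers(report, 1.0)), 3L)
})

test_that("evaluate_subset is deterministic and near-chance on noise", {
  set.seed(58)
  d <- null_dataset(200, 4)
  e1 <- evaluate_subset(d, c(1L, 2L), n_repeats = 20, seed = 21)
  e2 <- evaluate_subset(d, c(1L, 2L), n_repeats = 20, seed = 21)
  expect_identical(e1, e2)
  expect_gt(e1$mean_auc, 0.40)
  expect_lt(e1$mean_auc, 0.60)
  expect_error(evaluate_subset(d, integer(0)), class = "synet_input_error")
})

test_that("a perfectly predictive feature scores near 1 under subset CV", {
  set.seed(59)
  n <- 100
  y <- rep_len(c(0L, 1L), n)
  X <- cbind(y + rnorm(n, sd = 0.05), rnorm(n))
  d <- case_control_dataset(X, y)
  e <- evaluate_subset(d, 1L, n_repeats = 10, seed = 22)
  expect_gte(e$mean_accuracy, 0.95)
})

test_that("exhaustive_search dominates any fixed subset on identical folds", {
  set.seed(60)
  cfg <- sim_config(n_features = 4, n_samples = 120, n_synergy_pairs = 1)
  d <- simulate_dataset(cfg, draw_ground_truth(cfg, 7), 8)
  best <- exhaustive_search(d, "auc", n_repeats = 5, seed = 31)
  for (sub in list(1L, c(1L, 2L), c(2L, 3L, 4L), 1:4)) {
    e <- evaluate_subset(d, sub, n_repeats = 5, seed = 31)
    expect_gte(best$score, e$mean_auc - 1e-12)
  }
  expect_error(exhaustive_search(null_dataset(40, 17), "auc"),
               class = "synet_complexity_guard_error")
})

test_that("exhaustive_search recovers a strongly planted pair", {
  set.seed(61)
  hits <- 0L
  for (k in 1:10) {
    n <- 250
    X <- matrix(rnorm(n * 4), n, 4)
    y <- rbinom(n, 1, plogis(3 * X[, 1] * X[, 2]))
    if (length(unique(y)) < 2) next
    d <- case_control_dataset(X, y)
    best <- exhaustive_search(d, "auc", n_repeats = 3, seed = k)
    if (all(c(1L, 2L) %in% best$subset)) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
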