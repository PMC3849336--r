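#' Simulation configuration
#'
#' Describes the case-control disease model used to validate the method:
#' features are i.i.d. draws from an equal-weight two-component Gaussian
#' mixture (means -1 and +1, common variance 1), and the outcome follows
#' \deqn{\log\frac{p(y=1|v)}{1-p(y=1|v)} = \alpha_0 + \sum_i \alpha_i v_i
#'   + \sum_{i<j} \beta_{ij} v_i v_j,}
#' with `n_synergy_pairs` interaction coefficients and `individual_effects`
#' individual coefficients drawn from N(0, 1) on randomly chosen supports
#' and all remaining coefficients zero.  Defaults are the reference design:
#' 30 features, 200 samples, 10 synergistic pairs (so 425 of the 435 pair
#' coefficients are zero), no individual effects, \eqn{\alpha_0 = 0}.
#'
#' @param n_features number of features (default 30).
#' @param n_samples samples per dataset (default 200).
#' @param n_synergy_pairs nonzero interaction coefficients (default 10).
#' @param individual_effects nonzero individual coefficients (default 0;
#'   the second reference ensemble uses 5).
#' @param alpha0 intercept (default 0).
#' @param mixture_means means of the two mixture components.
#' @param mixture_sd common component standard deviation.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_features = 30L, n_samples = 200L,
                       n_synergy_pairs = 10L, individual_effects = 0L,
                       alpha0 = 0, mixture_means = c(-1, 1),
                       mixture_sd = 1) {
  n_features <- as.integer(n_features)
  n_pairs <- n_features * (n_features - 1L) / 2L
  if (n_features < 2L || n_samples < 20L) {
    synet_error("synet_input_error", "need n_features >= 2 and n_samples >= 20")
  }
  if (n_synergy_pairs < 0L || n_synergy_pairs > n_pairs) {
    synet_error("synet_input_error",
                sprintf("n_synergy_pairs must be in [0, %d]", n_pairs))
  }
  if (individual_effects < 0L || individual_effects > n_features) {
    synet_error("synet_input_error", "invalid individual_effects count")
  }
  structure(list(n_features = n_features, n_samples = as.integer(n_samples),
                 n_synergy_pairs = as.integer(n_synergy_pairs),
                 individual_effects = as.integer(individual_effects),
                 alpha0 = alpha0, mixture_means = mixture_means,
                 mixture_sd = mixture_sd),
            class = "sim_config")
}

#' Draw ground-truth coefficients
#'
#' Chooses `n_synergy_pairs` distinct unordered feature pairs uniformly
#' without replacement and gives them N(0, 1) interaction coefficients;
#' likewise for the `individual_effects` individual coefficients.  All
#' other coefficients are exactly zero.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (same seed, same truth).
#' @return an object of class `ground_truth`: `alpha` (length n),
#'   `beta_pairs` (data frame `i`, `j`, `beta` with `i < j`), `alpha0`.
#' @export
draw_ground_truth <- function(config, seed) {
  n <- config$n_features
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  withr::with_seed(as.integer(seed), {
    sel <- sample.int(nrow(pairs), config$n_synergy_pairs)
    beta <- stats::rnorm(config$n_synergy_pairs)
    supp <- sample.int(n, config$individual_effects)
    aval <- stats::rnorm(config$individual_effects)
  })
  alpha <- numeric(n)
  alpha[supp] <- aval
  beta_pairs <- data.frame(i = pairs[sel, "row"], j = pairs[sel, "col"],
                           beta = beta)
  structure(list(alpha = alpha, beta_pairs = beta_pairs,
                 alpha0 = config$alpha0),
            class = "ground_truth")
}

#' Simulate one case-control dataset
#'
#' Features are drawn from the mixture model of the configuration, the
#' per-sample success probability from the sparse interaction logit, and
#' the outcome from a Bernoulli draw.  By the symmetry of features,
#' coefficients and the logistic link the datasets are balanced in
#' expectation (\eqn{p(y=1) = p(y=0)}).
#'
#' @param config a [sim_config()].
#' @param truth a [draw_ground_truth()] result with matching dimensions.
#' @param seed integer seed.
#' @return a [case_control_dataset()] with attribute `"probabilities"`
#'   carrying the true per-sample \eqn{p(y=1|v)}.
#' @export
simulate_dataset <- function(config, truth, seed) {
  n <- config$n_samples
  p <- config$n_features
  if (length(truth$alpha) != p) {
    synet_error("synet_input_error", "ground truth does not match config dimensions")
  }
  withr::with_seed(as.integer(seed), {
    comp <- matrix(sample(config$mixture_means, n * p, replace = TRUE), n, p)
    V <- comp + matrix(stats::rnorm(n * p, sd = config$mixture_sd), n, p)
    logit <- truth$alpha0 + drop(V %*% truth$alpha)
    for (k in seq_len(nrow(truth$beta_pairs))) {
      logit <- logit + truth$beta_pairs$beta[k] *
        V[, truth$beta_pairs$i[k]] * V[, truth$beta_pairs$j[k]]
    }
    prob <- stats::plogis(logit)
    y <- stats::rbinom(n, 1L, prob)
  })
  # a Bernoulli draw can come out single-class on tiny n; the reference
  # design (n = 200, balanced) makes this astronomically unlikely
  ds <- case_control_dataset(V, y, sprintf("f%02d", seq_len(p)))
  attr(ds, "probabilities") <- prob
  ds
}

#' Generate an ensemble of simulated datasets
#'
#' Independent ground truths (fresh random coefficient values and supports)
#' and datasets per element, with per-element seeds derived from the master
#' seed so no two elements share an RNG stream.
#'
#' @param config a [sim_config()].
#' @param n_datasets ensemble size (default 20, the reference design).
#' @param seed master seed; identical seeds give bit-identical ensembles.
#' @return list of `n_datasets` elements, each a list with `dataset` and
#'   `truth`.
#' @export
generate_ensemble <- function(config, n_datasets = 20L, seed = 1L) {
  seeds <- matrix(derive_seeds(seed, 2L * n_datasets), ncol = 2L)
  lapply(seq_len(n_datasets), function(k) {
    truth <- draw_ground_truth(config, seeds[k, 1L])
    list(dataset = simulate_dataset(config, truth, seeds[k, 2L]),
         truth = truth)
  })
}
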