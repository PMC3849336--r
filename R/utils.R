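#' @noRd
synet_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "synergynet_error")))
}

#' Derive child seeds from a master seed
#'
#' Every stochastic operation in the package is a pure function of its inputs
#' and a seed.  Child seeds for sub-streams (datasets of an ensemble, CV
#' repeats, inner-CV fold assignments) are drawn deterministically from the
#' master seed so that no two sub-streams share an RNG state.
#'
#' @param seed integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds, separately permuting cases and
#' controls so class proportions are preserved across folds (unbalanced data
#' would otherwise risk single-class folds).
#'
#' @param outcome binary 0/1 vector.
#' @param k number of folds.
#' @param seed integer seed fixing the assignment.
#' @return integer vector of fold ids in `1..k`.
#' @keywords internal
stratified_folds <- function(outcome, k, seed) {
  folds <- integer(length(outcome))
  withr::with_seed(as.integer(seed), {
    for (cls in c(0L, 1L)) {
      idx <- which(outcome == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}
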