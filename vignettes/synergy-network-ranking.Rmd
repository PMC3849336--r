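---
title: "Synergy-network feature ranking: model, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synergy-network feature ranking: model, protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Classical risk-factor screening ranks candidate biomarkers one at a time by
the strength of their marginal association with a binary disease outcome.
This misses variables whose individual effect is negligible but whose
*pairwise synergy* carries real predictive signal — a pattern seen in
complex diseases such as type 1 diabetes, where immunologic and metabolic
indices interact. `synergynet` implements a network-based alternative: it
quantifies both individual and pairwise synergistic effects, assembles them
into a single weighted graph, and ranks features by a spectral relaxation of
a best-subnetwork objective.

## The synergy network

For a dataset of features $v_1,\dots,v_n$ and outcome $y \in \{0,1\}$:

* **node weight** $f(v_i) = -\log p_i$, where $p_i$ is the coefficient
  p-value of $\alpha_1$ in the single-variable logistic model
  $\log(g/(1-g)) = \alpha_0 + \alpha_1 v_i$;
* **edge weight** $s(v_i,v_j) = -\log p_{ij}$, where $p_{ij}$ is the
  coefficient p-value of the interaction term $\beta$ in
  $\log(g/(1-g)) = \alpha_0 + \alpha_1 v_i + \alpha_2 v_j + \beta v_i v_j$
  (the main-effect p-values of this model are discarded).

With $n$ features there are exactly $n(n-1)/2$ edges (435 for $n = 30$,
171 for $n = 19$).

Choices the underlying publication left open, fixed here as follows:

* **Test type.** "Coefficient p-value" is read as the two-sided Wald test
  from the estimated coefficient covariance — the default report of any
  standard logistic fit. A likelihood-ratio alternative is available via
  `test = "lrt"`.
* **Logarithm base.** Natural log. The base uniformly rescales all weights
  and cannot change any ranking, so the choice is documented but inert.
* **p-value floor.** p-values are capped below at `p_floor = 1e-300` so
  weights stay finite under underflow.
* **Separation and non-convergence.** Complete separation is detected
  directly (all fitted probabilities saturate at their outcomes) and
  assigned `p = p_floor`: the term is maximally significant and the cap is
  what keeps its weight finite. We deliberately do *not* compute a Wald
  p-value from a ridge-penalized refit here — under complete separation the
  penalty dominates the curvature and the resulting p-value is
  meaninglessly large. Plain non-convergence without separation is retried
  with a small ridge (`1e-4`) on the slopes; rank-deficient designs (e.g. a
  product term collinear with the main effects) get weight 0 with a
  warning. Zero weight is conservative: a failed fit never promotes a
  feature.
* **No centering or standardization.** The interaction p-value is not
  invariant to centering, and the model is presented on raw variables;
  features are used exactly as given.
* **$\lambda$ default.** The individual-vs-synergy weighting $\lambda$
  defaults to 1 (equal weighting). No value is singled out by the main
  analysis being reproduced; $\lambda$ is exposed everywhere and a sweep is
  a loop over `build_network(lambda = ...)`.

## From subnetworks to a spectral ranking

The best biomarker subnetwork $C$ maximizes
$$\sum_{v_i \in C} f(v_i) + \lambda \sum_{v_i,v_j \in C} s(v_i,v_j),
\qquad |C| \le K,$$
a size-constrained maximum weighted clique problem (NP-hard).
`solve_exact()` enumerates subsets exactly for $n \le 25$ and is the oracle
the relaxation is tested against. Writing the subset as a binary indicator
vector $x$ and relaxing it to a real unit vector turns the objective into
$\max_x x^\top M x$ with $M_{ii} = f(v_i)$, $M_{ij} = \lambda\, s(v_i,v_j)$;
the KKT condition makes the optimum the leading eigenvector $x^*$ of $M$.
`rank_features()` ranks features by $|x^*_i|$. Because $x^*$ does not
depend on $K$, the ranking is $K$-free; $K$ matters only to `solve_exact()`
and `spectral_topk()`.

Numerical conventions:

* **Tie-break:** score descending, then node weight descending, then
  feature index — deterministic and documented. Scores are rounded to 12
  decimal places for ordering only, so exact degeneracies (e.g. a uniform
  Perron vector) are broken by the documented rule rather than by
  eigen-solver noise at `1e-16`.
* **Degenerate spectrum:** if the top two eigenvalues are within
  $10^{-10}\,\|M\|_F$ the ranking is flagged `unstable`.
* **Diagonal fallback:** for $\lambda = 0$ (or an all-zero edge matrix) $M$
  is diagonal and its leading eigenvector is a coordinate vector, which
  ranks a single feature; the ranking then falls back to ordering by
  individual power, preserving the intent that $\lambda = 0$ reduces to the
  classical individual ranking (`diagonal_fallback_used = TRUE`).

## Selection and the embedded cross-validation protocol

`forward_select()` walks once down a ranked list and accepts a candidate
iff it *strictly* improves (by more than $\varepsilon = 10^{-12}$) the
inner stratified ten-fold cross-validated metric of a QDA classifier over
the current best, scoring all candidates on identical folds fixed by the
seed. Strictness avoids bloating the set through ties; a single pass with
no revisiting matches the "until the end of the ranked list" procedure.

**The empty set scores 0**, so the top-ranked candidate always enters. This
is a load-bearing choice: when the signal is purely synergistic, no single
feature beats a majority-classifier baseline (~0.52 on near-balanced data),
so a baseline-anchored rule would reject the first member of every
interacting pair and no pair could ever assemble. With the zero baseline
the first member enters on rank evidence, and its partner is then accepted
on genuine improvement. Desk-scale experiments during development showed
the baseline-anchored variant loses ~9 accuracy points on purely
synergistic data while the zero-baseline rule reproduces the reference
results; see the decisions ledger of the repository for the measurement.
A corollary is that selections are never empty and pure-noise data yield
small but nonzero selections (measured mean ≈ 5 of 30 candidates — the
record-chain behaviour of noisy CV estimates), which the tests assert as
the observed behaviour.

`embedded_cv()` wraps ranking *and* selection inside every outer training
fold: per repeat, a stratified ten-fold split; per fold, the synergy
network is rebuilt and features re-ranked on the nine training folds only,
forward selection runs with its own inner ten-fold CV inside the training
portion, a QDA model is refit on the training portion restricted to the
selected features, and accuracy and AUC are recorded on the held-out fold.
Stratification is used in both layers because unbalanced data would
otherwise risk single-class folds. A fold whose selection were empty
(impossible under the zero baseline, kept for robustness) would score as
the training-majority classifier with AUC 0.5. Repeating $R$ times yields
$R \times 10$ selected subsets; `consensus_biomarkers()` keeps features
appearing in at least 40% of them (inclusive threshold).

The classifier is QDA — chosen because class-specific covariances give
quadratic boundaries that can exploit pairwise interactions. Per-class
covariances are shrunk toward $(\mathrm{tr}\,S/d)\,I$ with coefficient
`1e-4`, escalated (`1e-2`, `1e-1`, `0.5`) only if the Cholesky
factorization fails. This diverges deliberately from MATLAB's `classify`,
which errors on singular covariances: forward selection must be free to
probe subsets that are large relative to a fold. Predictions threshold the
posterior at 0.5.

**AUC convention.** The public `auc_score()` is the standard Mann–Whitney
statistic (ties counted 1/2) on arbitrary scores. Inside the evaluation
protocol, however, AUC is computed by default from the 0.5-thresholded
*predictions* (`auc_from = "labels"`), i.e. it equals balanced accuracy.
This reproduces the reference results, whose accuracy and AUC values
coincide to about three decimals on balanced data — a signature of
label-based AUC that a continuous-score AUC cannot produce (in our
experiments posterior-score AUC runs 5–8 points higher than accuracy on
the same folds). `auc_from = "posterior"` switches the protocol to the
continuous Mann–Whitney AUC when the conventional measure is wanted.

The paired network-vs-individual comparison emitted by the CLI uses a
two-sided Wilcoxon signed-rank test across outer-fold scores — a
documented convention, since the comparison test behind the reference
p-values is unnamed in the source material.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the validation design: 30 features drawn
i.i.d. from an equal-weight mixture of $N(-1,1)$ and $N(+1,1)$ (mean 0,
variance 2), 200 samples per dataset, and the outcome drawn from
$$\text{logit}\, p(y{=}1\mid v) = \alpha_0 + \sum_i \alpha_i v_i +
\sum_{i<j} \beta_{ij} v_i v_j,$$
with 10 of the 435 pair coefficients (and 0 or 5 of the individual
coefficients; ensembles A and B) drawn from $N(0,1)$ on uniformly chosen
supports, all else zero, $\alpha_0 = 0$. The interaction sum is one term
per unordered pair: the design statement fixes 435 free coefficients, and
the doubled (ordered-sum) reading measurably overshoots the reference
performance levels. Interacting pairs may share features — sampling is
over pairs, not a matching. By symmetry of the features, the coefficients
and the logistic link, $p(y{=}1) = p(y{=}0)$, so the datasets are balanced
in expectation and accuracy tracks AUC.

The simulator does *not* emulate correlated feature blocks, non-Gaussian
marginals, covariate confounding or missingness. A green test on this
generator therefore establishes that the pipeline recovers sparse pairwise
synergies among independent mixture-Gaussian features at $n = 200$; it
says nothing about collinear panels or heavy-tailed assays.

Every stochastic operation is a pure function of its inputs and a seed;
sub-streams (ensemble elements, CV repeats, inner fold assignments) use
child seeds derived deterministically from the master seed
(`derive_seeds()`), so no two sub-streams share RNG state and every report
is bit-reproducible from its config block.

## Known limitations

* Only pairwise synergies enter the network; third-order interactions are
  invisible to both the fits and the ranking.
* Forward selection is greedy and order-dependent: a pair whose two members
  are ranked far apart can still be missed if the early member is rejected
  before its partner appears (no revisiting).
* The exact solver is exponential and guarded at 25 features; exhaustive
  subset search is guarded at 16.
* Wald p-values at small $n$ ($\lesssim 50$ per fit) can be conservative in
  the extreme tails; the `lrt` switch is provided for sensitivity checks.
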