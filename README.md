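# synergynet

Network-based feature ranking for case-control biomarker discovery.

Classical risk-factor screening ranks candidate biomarkers by their
marginal association with a binary outcome and misses variables whose
individual effect is weak but whose *pairwise synergy* is predictive.
`synergynet` targets exactly those variables. It is aimed at
biostatisticians and epidemiologists analyzing moderate panels (tens of
features) of clinical or molecular measurements against a binary outcome
such as disease onset.

## Method

For features $v_1,\dots,v_n$ and outcome $y\in\{0,1\}$ the package builds a
**synergy network** $G(V,E)$:

* node weights $f(v_i) = -\log p_i$, with $p_i$ the Wald p-value of
  $\alpha_1$ in $\operatorname{logit} g = \alpha_0 + \alpha_1 v_i$;
* edge weights $s(v_i,v_j) = -\log p_{ij}$, with $p_{ij}$ the p-value of
  the interaction coefficient $\beta$ in
  $\operatorname{logit} g = \alpha_0 + \alpha_1 v_i + \alpha_2 v_j + \beta v_i v_j$.

The best biomarker subnetwork maximizes
$\sum_{v_i\in C} f(v_i) + \lambda \sum_{v_i,v_j\in C} s(v_i,v_j)$ subject to
$|C|\le K$ — a maximum weighted clique problem (NP-hard; an exact solver is
included for $n \le 25$). Relaxing the binary indicator to a real unit
vector reduces the objective to the leading eigenvector $x^*$ of the matrix
$M$ with $M_{ii}=f(v_i)$, $M_{ij}=\lambda\,s(v_i,v_j)$; features are ranked
by $|x^*_i|$, independently of $K$. The ranked list feeds a forward feature
selection evaluated by **embedded ten-fold cross-validation** (network and
ranking rebuilt inside every outer training fold; inner ten-fold CV scores
candidates; QDA classifier; accuracy and AUC on held-out folds), so
reported performance is leakage-free. A mixture-of-Gaussian case-control
simulator with sparse pairwise logistic interactions reproduces the
validation benchmarks. See the vignette
(`vignettes/synergy-network-ranking.Rmd`) for assumptions and design
choices.

## Worked example

```r
library(synergynet)

cfg   <- sim_config(n_features = 12, n_samples = 200, n_synergy_pairs = 3)
truth <- draw_ground_truth(cfg, seed = 42)
ds    <- simulate_dataset(cfg, truth, seed = 43)
truth$beta_pairs
#>    i  j      beta
#> 1  4 11 0.3631284
#> 2 10 12 0.6328626
#> 3  4  8 0.4042683

nw <- build_network(ds, lambda = 1)
rk <- rank_features(nw)
rk
#> spectral_ranking: 12 features, leading eigenvalue 21.0456
#>   top: f10 (0.630), f12 (0.561), f05 (0.250), f08 (0.218), f11 (0.207)

rep <- embedded_cv(ds, "network", "auc", n_repeats = 5, seed = 7)
rep
#> evaluation_report: network ranking, auc-guided selection, lambda = 1
#>   5 repeats x 10 folds (50 subsets); mean accuracy 0.6813 (sd 0.0923), mean AUC 0.7473 (sd 0.1116)
#>   consensus (>= 40%): f05, f10, f12

embedded_cv(ds, "individual", "auc", n_repeats = 5, seed = 7)$mean_auc
#> [1] 0.6618
```

The strongest planted pair (f10, f12; $\beta = 0.63$) tops the spectral
ranking and lands in the consensus set, and the network ranking beats the
individual-power baseline by ~0.085 AUC on held-out folds — the package's
central claim in miniature. (f05 enters through its marginal association in
this particular draw.)

A command-line wrapper covering `simulate`, `network`, `rank`, `select` and
`evaluate` is installed at `inst/cli/synergynet`:

```sh
Rscript inst/cli/synergynet simulate --out sim/ --datasets 1 --seed 3
Rscript inst/cli/synergynet evaluate --data sim/dataset_01.csv \
    --ranking both --metric auc --repeats 10 --seed 5 --out report.json
```

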