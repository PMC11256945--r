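# deepIDA

Joint nonlinear association and discrimination for multi-view data, with
bootstrap permutation feature ranking.

Biomedical studies increasingly measure several data *views* — proteomics,
metabolomics, RNA-seq — on the same samples, alongside a categorical
outcome. `deepIDA` trains one feed-forward network per view so that the
learned low-dimensional representations simultaneously (i) separate the
outcome classes within each view and (ii) correlate across views, then
classifies by nearest centroid in the learned space and ranks input
features by how often permuting them degrades out-of-bag classification.

## The objective in brief

With top-layer representations $H_d = f_d(X_d)$, between-class and total
covariances $S_{bd}$, $S_{td}$ (centered at the mean of class means) and
cross-covariances $S_{dj}$, define the whitened operators
$M_d = S_{td}^{-1/2} S_{bd} S_{td}^{-1/2}$ and
$N_{dj} = S_{td}^{-1/2} S_{dj} S_{tj}^{-1/2}$. Projections
$\Gamma_d$ (orthonormal, $l \le \min\{K-1, o_d\}$ columns) and network
parameters maximize

$$
\frac{\rho}{D}\sum_d \mathrm{tr}\,[\Gamma_d^\top M_d \Gamma_d]
+ \frac{2(1-\rho)}{D(D-1)} \sum_{d<j}
\mathrm{tr}\,[\Gamma_d^\top N_{dj}\Gamma_j\Gamma_j^\top N_{dj}^\top\Gamma_d],
$$

solved by alternating symmetric eigenproblems in $\Gamma$ and full-batch
gradient ascent on the sum of leading eigenvalues in the network weights
(analytic gradients through the covariances, the inverse matrix square
root, and the eigenvalues — no autodiff framework required). The
`vignettes/deepIDA-methods.Rmd` vignette derives the procedure and records
every numerical choice.

## Worked example

A reduced instance of the built-in nonlinear two-view simulation (two
spiral-arm classes; the first 10% of view-1 columns are signal, view 2 is
a rectified noisy derivative of view 1 with no signal of its own):

```r
library(deepIDA)

set   <- sim_setting("S1", n1 = 150, n2 = 120, p1 = 120, p2 = 120)
train <- generate_nonlinear(set, seed = 1)
test  <- generate_nonlinear(set, seed = 2)

specs <- lapply(train$views, function(X) network_spec(ncol(X), c(64, 32), 10))
model <- train_deep_ida(train$views, train$labels, specs = specs,
                        config = train_config(epochs = 60, learning_rate = 1e-2,
                                              ridge = 1, weight_decay = 1e-2,
                                              seed = 1))
model
#> deep_ida_model: 2 views, 2 classes, rho = 0.50, l = 1
#>   final loss -1.41484 after 60 epochs

res <- ncc_classify(model, train$views, train$labels, test$views, "view", 1)
met <- classification_metrics(test$labels, res$class, res$decision_values)
round(unlist(met[c("accuracy", "balanced_accuracy", "auroc", "f1")]), 3)
#>          accuracy balanced_accuracy             auroc                f1
#>             0.807             0.807             0.868             0.787
```

The loss is the negative sum of leading eigenvalues of the combined
separation + association operator (its lower bound here is $-1.5$), and
the test accuracy is nearest-centroid accuracy on the view-1
representations of an independently generated test set. Feature ranking
on the same training data:

```r
rk <- bibootstrap_rank(train,
        deep_ida_trainer(config = train_config(epochs = 20, learning_rate = 1e-2,
                                               standardize = FALSE, seed = 1),
                         spec_builder = function(p, n) network_spec(p, c(64, 32), 10)),
        ranking_config(M = 10, seed = 1))
head(rk$views[[1]][order(rk$views[[1]]$rank),
                   c("feature", "n_k", "N_k", "proportion", "rank")], 5)
#>     feature n_k N_k proportion rank
#> 4         4   8   9  0.8888889    1
#> 5         5   7   8  0.8750000    2
#> 111     111   6   8  0.7500000    3
#> 1         1   5   7  0.7142857    4
#> 2         2   5   7  0.7142857    5

sel <- select_top(rk, top_fraction = 0.10)[[1]]
round(unlist(selection_metrics(sel, train$signal_masks[[1]])), 3)
#>   tpr   fpr    f1
#> 0.667 0.037 0.667
```

`proportion` is the fraction of out-of-bag permutation evaluations in
which shuffling that feature strictly decreased the classification rate;
the true signals here are features 1–12. At this demonstration scale
($M = 10$ pairs, 120 features) the selection recovers two thirds of the
signals with almost no false positives; at the full simulation scale
($M = 20$, 500 features) the same pipeline recovers essentially all of
them (see below).

A command-line wrapper ships in `inst/cli/deepida.R`
(`simulate`, `train`, `rank`, `evaluate`, `reproduce` subcommands).

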