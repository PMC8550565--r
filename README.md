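# dvmetric

Quantify how much useful information a dataset actually carries for a
specific inferential task.

A 70% classification accuracy does not tell you whether more samples, more
features, or a different model would help — the performance of the *model*
is not the sufficiency of the *data*. `dvmetric` implements the **Data
Value Metric (DVM)**, an information-theoretic score for a (dataset,
method) pair that addresses exactly this question for biostatistical and
machine-learning workflows: learning-curve planning, data-augmentation
decisions, and feature selection.

The metric blends an information-bottleneck fidelity with a normalized
computational-complexity penalty:

```
DVM(D) = F(D) − λ·R(D),      F = ( I(T;Y) − β·I(X;T|Y) ) / I(X;Y)
```

where `X` are the features, `Y` the labels, and `T` the representation a
fitted model produces on held-out samples (its predicted labels by
default). `F` is estimated over `M` repeated seeded splits with a 95%
confidence interval, normalized by the full-data mutual information
`I(X;Y)`, and is bounded above by 1 for deterministic representations;
`R ∈ [0,1]` is the log-normalized Big-O training cost of the chosen method.
For clustering, the same ratio is computed from two independent fits
applied to a common held-out part — a relabeling-invariant measure of
cluster stability.

The package ships:

* three mutual-information estimators — exact **plug-in** for categorical
  data, **KSG** (k-nearest-neighbour, compiled) for continuous pairs, and a
  **hash/binning ensemble** (random projection + multi-resolution
  quantization) for mixed or high-dimensional data — plus chain-rule
  conditional MI;
* supervised (repeated stratified splits) and unsupervised (three-way
  splits) fidelity procedures, the complexity registry, and `compute_dvm()`;
* DVM-driven greedy **forward feature selection** with a full trace;
* seeded **synthetic benchmark generators** (Gaussian blobs, cube-root
  regression, 4-cluster square) and a config-driven **surface runner**
  mapping DVM/accuracy over sample-size × feature-count grids;
* tidyverse-native interfaces: tibbles in and out, `tidy()` / `glance()`
  accessors, `autoplot()` methods, and a thin `dvm` command-line tool
  (`inst/cli/dvm`) with `simulate` / `dvm` / `surface` / `select-features`
  subcommands driven by validated YAML configs.

## Worked example

```r
library(dvmetric)

# 4 Gaussian clusters at the corners of a unit square, hidden in 2 of 10
# coordinates; the other 8 are pure noise.
d <- simulate_cluster_square(n = 400, d = 10, seed = 42)

res <- compute_dvm(d, dvm_model("random_forest", k_trees = 100),
                   cfg = fidelity_config(seed = 42))
res
#> <dvm_result> random_forest (supervised), n = 400, p = 10
#>   DVM      : 0.9746  (fidelity 0.9846 - lambda 0.01 x regularizer 1.0000)
#>   fidelity : 0.9846  [95% CI 0.9664, 1.0028] over 10 splits
#>   accuracy : 0.9942  (mean held-out, same splits)
```

Read: the random forest recovers essentially all of the task information
the dataset carries (fidelity ≈ 0.98 of the normalizing `I(X;Y)`), at the
reference complexity (regularizer = 1 on the full data), so the penalized
score is 0.975 — adding samples to *this* dataset would buy little. The
per-split values behind the CI are available via `tidy(res)`, a one-row
summary via `glance(res)`, and a plot via `autoplot(res)`.

Forward selection finds the two informative coordinates immediately:

```r
tr <- select_features(d, dvm_model("decision_tree"), r = 5,
                      cfg = fidelity_config(n_splits = 5, seed = 42))
tr
#> <dvm_selection> 5 steps (decision_tree), peak DVM = 0.9714 at step 4
#>   best subset: F4, F8, F2, F7
#>  step feature       dvm
#>     1      F4 0.4630903
#>     2      F8 0.9347795
#>     3      F2 0.9298084
#>     4      F7 0.9714306
#>     5      F1 0.9554368

attr(d, "informative")
#> [1] "F4" "F8"
```

One corner coordinate alone carries about half the cluster information
(DVM 0.46); the pair jumps to 0.93; later noise features add nothing and
the non-monotone tail is the expected complexity/compression penalty at
work. The same run is available from a shell:

```sh
dvm select-features --config run.yml --seed 42 --output-dir out/
```

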