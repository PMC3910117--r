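# sinetrend

Nonlinear model-based analysis of time-course gene expression profiles.

Expression measured across a dynamic biological process — the classic
example is the alpha-factor–synchronised yeast cell division cycle —
often combines a periodic component whose amplitude decays (or grows)
over time with a slow linear drift. `sinetrend` models each gene's
profile with a damped sinusoid plus linear trend,

```
x(t) = e^{αt} [ a·cos(ωt) + b·sin(ωt) ] + c·t + d + ε(t),   ε(t) ~ N(0, σ²)
```

where `α` is the degradation rate of the periodicity, `ω` the angular
frequency, `√(a² + b²)` and `arctan(a/b)` the magnitude and phase of the
oscillation, and `c`, `d` the linear trend. Three analyses are built on
the model:

* **Parameter estimation** — a two-step linear least-squares method. The
  noise-free model is the general solution of the second-order ODE
  `ẍ + Aẋ + Bx = Ct + D`, whose coefficients are *linear* in the data
  once derivatives are estimated by central finite differences. Step 1
  regresses the differenced second derivative on `[-ẋ, -x, t, 1]` to get
  `(A, B, C, D)`, hence `α = -A/2`, `ω = √(4B - A²)/2`, `c = C/B`,
  `d = D/B - AC/B²`; Step 2 linearly regresses the detrended, de-damped
  signal on `cos(ωt)`, `sin(ωt)` to get `(a, b)`. No iterative nonlinear
  optimisation, hence no starting values and no local minima. Profiles
  whose Step-1 estimate falls outside the oscillatory regime
  (`4B - A² ≤ 0`) are flagged *degenerate*: not describable by the model.
* **Significance screening** — an F test of the 6-parameter model against
  the constant-plus-white-noise null `x(t) = d + ε(t)`, with
  `F = ((S₀² - S₁²)/5) / (S₁²/(m - 6))` referred to F(5, m − 6); genes
  above the upper-γ critical value are called model-following
  (e.g. periodically expressed), the rest noise.
* **Model-based clustering** — a relocation-iteration algorithm that
  alternates pooled per-cluster parameter estimation (summed
  normal-equation terms over members) with reassignment of every profile
  to the cluster curve with the smallest squared residual, run from many
  random (or k-means) initial partitions.

Synthetic-data generators reproduce the two benchmark designs (a
2000 + 2000 noise/signal mixture for the screen; a six-cluster dataset
with jittered per-cluster parameters), and evaluation utilities provide
sensitivity/specificity threshold sweeps, the Hubert–Arabie adjusted
Rand index (ARI) and its average over repeated runs (AARI).

## Worked example

Screen a simulated mixture of 100 noise and 100 model-following
profiles (18 time points, noise sd 0.5, oscillation magnitude 1–2):

```r
library(sinetrend)
sim <- generate_mixed_dataset(n_noise = 100, n_signal = 100, seed = 7)
res <- classify_profiles(sim$dataset, gamma = 0.1)
table(truth  = ifelse(sim$truth, "model", "noise"),
      called = ifelse(res$significant, "significant", "noise"))
#>        called
#> truth   noise significant
#>   model    63          37
#>   noise    98           2
```

At this noise level the screen is conservative: the false-positive rate
(2/100) sits well under γ = 0.1, while power against the harder, decaying
signals is partial (37/100) — see the methods vignette for why the
two-step residual makes the test conservative. Cluster a three-group
dataset and compare with the generating labels:

```r
sim <- generate_cluster_dataset(K = 3, sizes = rep(40, 3), seed = 11)
cl  <- cluster_with_restarts(sim$dataset, K = 3, n_restarts = 10, seed = 1)
cl
#> <tc_clusters> K = 3, cost = 547.753, 4 iteration(s), converged
#> sizes: 40 40 40
round(cluster_param_table(cl), 3)
#>   cluster size  alpha omega      a      b      c      d
#> 1       1   40 -0.057 0.915  1.475 -0.574  0.053 -0.430
#> 2       2   40 -0.014 0.832 -0.522 -0.544 -0.049 -0.223
#> 3       3   40 -0.223 0.950 -0.295 -0.455  0.006  0.812
adjusted_rand_index(cl$labels, sim$truth)
#> [1] 1
```

Each row of the cluster table is one fitted model: cluster 3, for
instance, decays fastest (`alpha = -0.223`) while cluster 1 carries the
largest oscillation magnitude.

The same pipeline is available from a shell via the bundled script
(`inst/cli/sinetrend` after installation): subcommands `simulate`,
`fit`, `significance`, `cluster` and `evaluate`, e.g.

```sh
sinetrend significance --in expression.tsv --out screen.tsv --gamma 0.1
sinetrend cluster --in expression.tsv --out run --k 5 --restarts 30 --seed 1
```

Input is tab-separated text with a header line, a gene-identifier column
and numeric time-point columns; rows with missing values are excluded and
recorded, the standard preprocessing for public cell-cycle matrices.

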