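# tsee — time series elastic embedding for single-cell expression data

Time series scRNA-seq experiments collect cells at a handful of
experimental stages along a developmental process. Two things routinely
degrade a purely expression-driven 2-D map of such data: batch-like
distortion that differs between collection stages, and strong cell-to-cell
variability that makes cells from distant stages look alike. `tsee`
implements **time series elastic embedding (TSEE)**: elastic embedding
extended with a *temporal* repulsive force, so that cells collected far
apart in experimental time resist being placed side by side even when
their measured expression overlaps.

## The model

Given preprocessed expression vectors \(y_1,\dots,y_N\) with per-cell
normalized stage times \(t(n) \in [0,1]\), the embedding
\(X = (x_1,\dots,x_N) \in \mathbb{R}^{N\times d}\) minimizes the
pseudo-potential energy

```
E[X; λ, β] = Σ_{n,m} w⁺ₙₘ ‖xₙ − xₘ‖²  +  λ Σ_{n,m} (wₙₘ⁻ + β tₙₘ) exp(−‖xₙ − xₘ‖²)
```

with weights computed once from the input:

* attractive: `w⁺ₙₘ = N⁺ exp(−‖yₙ − yₘ‖² / 2σ²)` (Gaussian similarity),
* repulsive disparity: `wₙₘ⁻ = N⁻ ‖yₙ − yₘ‖`,
* temporal: `tₙₘ = N⁻ |t(n) − t(m)|`,

where `N⁺` and `N⁻` normalize the attractive weights and the combined
repulsive weights to sum to one. `λ` trades attraction against repulsion;
`β` weighs the experimental time interval within the repulsive term. With
`β = 0` the method is plain elastic embedding (EE); with `λ = 0` it reduces
to a Laplacian-eigenmap-style attraction-only problem. Defaults are
`λ = β = 10`.

The energy is minimized by a partial-Hessian *spectral direction*
iteration: the gradient has the graph-Laplacian form `∇E = 4LX`, the
search direction solves `(Lᴾ ⊗ I_d + μI) p = −g` against the (convex)
attractive Laplacian via one cached Cholesky factorization, and steps are
accepted by Armijo backtracking, giving a monotonically non-increasing
energy trace.

The package also provides the companion preprocessing pipeline
(variable-gene selection by variance Z-score → global min-max scaling →
PCA → min-max scaling), embedding quality metrics (in-group proportion
IGP, its time-adjacent relaxation IGP2, sample-weighted means, a
misplaced-cell diagnostic, complete-linkage trees over stage centroids), a
synthetic time-course generator with known latent structure, and
readers/writers plus a CLI for dense TSV/CSV and MatrixMarket expression
matrices.

## Worked example

Simulate a hard 5-stage time course — 300 cells, measurement noise on the
order of the expression dynamic range, plus a per-stage batch shift —
embed it with and without the temporal term, and score both maps:

```r
library(tsee)

sim <- simulate_timecourse(synthetic_config(noise_sd = 1.0, seed = 1))
#> synthetic_dataset: 300 cells, 50 genes (5 oscillatory), 5 stages, seed 1

fit <- fit_tsee(sim$dataset, embedding_config())        # λ = β = 10
#> embedding_result: 300 cells in 2-D, 37 iterations (converged), final energy 3.42919

metric_report(fit)
#> metric_report
#>   weighted mean IGP: 1
#>   IGP  per stage: 1 1 1 1 1
#>   IGP2 per stage: 1 1 1 1 1
#>   misplaced cells: 0 / 300

ee <- fit_tsee(sim$dataset, embedding_config(beta = 0)) # plain EE
metric_report(ee)
#> metric_report
#>   weighted mean IGP: 0.5533
#>   IGP  per stage: 0.545 0.592 0.476 0.565 0.592
#>   IGP2 per stage: 0.945 0.972 0.889 1.000 0.816
#>   misplaced cells: 21 / 300

ground_truth_pcc(fit, sim)   # 0.913
ground_truth_pcc(ee, sim)    # 0.821
```

With the temporal term every cell's nearest neighbor lies in its own stage
(weighted mean IGP 1.0, no misplaced cells) and the leading axis of the
map tracks the true latent time (PCC 0.91). The β = 0 baseline loses
stage purity under the same distortion (weighted mean IGP 0.55, 21 cells
whose nearest neighbor is ≥ 2 stages away) and orders the course less
faithfully (PCC 0.82).

For real data the same flow is
`preprocess_pipeline()` → `fit_tsee()` → `metric_report()`, or from a
shell via the CLI wrapper:

```sh
Rscript inst/cli/tsee.R preprocess --expression counts.tsv --labels stages.tsv --out pre.tsv
Rscript inst/cli/tsee.R embed --input pre.tsv --out embedding.tsv
Rscript inst/cli/tsee.R evaluate --embedding embedding.tsv --out metrics
```

Spatial (or any other) side information can replace the time-interval
matrix: pass a symmetric non-negative `side_distance` — e.g.
`1 − PCC` over spatial marker genes — to `build_affinities()` /
`fit_tsee()`.

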