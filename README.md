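# bicar

Reproducibility-ranked fusion of two datasets with complementary
spatiotemporal resolution.

## Who this is for

You have two recordings of one process: a **temporal** matrix `X_T`
(sensors × time samples — fast sampling, sparse coverage; think EEG or
ground sensors) and a **spatial** matrix `X_S` (frames × pixels — dense
coverage, slow sampling; think fMRI volumes or satellite images). No
dimension of one matrix need match any dimension of the other, so
concatenation-style joint decompositions would force arbitrary
resampling. `bicar` fuses them instead through a physical assumption:
the time course with which a source appears in the spatial frames is a
filtered, decimated version of its fast time course.

## The method

Both matrices follow the linear source-separation model
`X = A S + N` (mixing matrix `A`, standardized source rows `S`). The
pipeline:

1. run K independently seeded stochastic ICA decompositions of each
   matrix (symmetric fixed-point iteration, log-cosh contrast, whitening
   to `n_components`);
2. within each realization, pair every temporal source with a spatial
   source by greedy maximal `|Pearson|` between the transferred source
   `D F s` (convolution with a delayed gamma-variate filter
   `h(t) = (t−Δ)^a e^{−(t−Δ)/b} Θ(t−Δ)`, then decimation by `q`) and the
   spatial mixing columns;
3. compare matched pairs across all K(K−1)/2 realization pairs with
   cross-realization correlation matrices
   `R(ij)_rc = w_T |ρ_T| + w_S |ρ_S|`;
4. align one super-source per realization into each of `N_C` groups
   (global-maximum seed, then best row/column partners, masking as you
   go), canonicalize signs (flipping source and mixing column together),
   and collapse each group by similarity-weighted averaging.

Each fused component carries a **reproducibility** index
`R ∈ [0, 1]` — the mean pairwise similarity of its K aligned members —
and components are ranked by it: the more reproducible a component, the
more it resembles a true source. Recovery against a known ground truth
is scored by `Q = Q_T + Q_S` (greedy successive-maxima assignment of
half-temporal + half-spatial absolute correlations; each half bounded by
0.5).

Details, defaults and design rationale: `vignettes/bicar-methods.Rmd`.

## Worked example

Generate the built-in benchmark (five windowed waveforms mixed into 16
block sensors; five Gaussian-blob images mixed into 16 frames through
the transfer function) at SNR 100, run the pipeline, and score it:

```r
library(bicar)
sim <- simulate_blobs(seed = 3, sigma2 = 0.01)   # 1/SNR = 0.01
res <- bicar(sim$X_T, sim$X_S, n_components = 5,
             n_realizations = 30, master_seed = 7)
print(res)
#> <bicar_result: 5 components>
#> reproducibility: 1.000 1.000 1.000 1.000 1.000
quality(res, sim$truth)
#> <quality_report: Q = 0.9754 (Q_T = 0.4963, Q_S = 0.4791), 5/5 matched>
```

All five components are perfectly reproducible across the 30
realizations (this simple data has a single ICA optimum at low noise),
and the recovered pairs correlate with the generating sources at
`Q = 0.98` of a possible 1 — near-perfect recovery, split into a
temporal half (0.4963 of 0.5) and a spatial half (0.4791 of 0.5).

Experiment drivers reproduce the robustness studies:
`noise_sweep()` (quality vs 1/SNR over the grid 0.01–100),
`reproducibility_truth_correlation()` (over-extraction: do reproducible
components track true sources?), and `tf_mismatch_experiment()`
(generate with one transfer function, recover with a perturbed one).

## Command line

```sh
Rscript inst/cli/bicar simulate blobs --seed 7 --out data.h5
Rscript inst/cli/bicar run -c run.yaml --out result.h5
Rscript inst/cli/bicar evaluate --result result.h5 --truth data.h5 --out report.json
```

(after installation the script lives at
`system.file("cli", "bicar", package = "bicar")`). The YAML config holds
`n_components`, `n_realizations`, `master_seed`,
`weights: {w_T, w_S}`, `transfer: {a, b, delta, dt, q, conv_mode,
normalize}` and `paths: {input, output}`. HDF5 layouts: datasets `/X_T`,
`/X_S`, optional `/truth/{S_T,S_S,A_T,A_S,pairing,image_shape}`; results
`/result/{S_T,S_S,A_T,A_S,reproducibility}` plus a JSON provenance
sidecar and a `component,R` spectrum CSV.

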