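# radialrecon

Sparse-view dynamic radial MRI: simulation, reconstruction and evaluation.

Dynamic contrast-enhanced MRI shortens its per-frame acquisition by
measuring only a sparse set of radial k-space views (here 24 of the 72
needed for an alias-free image). This package implements, on a synthetic
first-pass perfusion phantom with known ground truth, the two standard ways
of reconstructing such data — and the evaluation protocol that exposes the
price each one pays:

* **Iterative Bayesian reconstruction** (`reconstruct()`): joint gradient
  descent over the complex image series on

  ```
  C = Σ_t ‖W_t ∘ F m_t − d_t‖² + α₁ Σ |∇_t m|² + α₂ Σ √(|∇_x m|² + |∇_y m|² + ε)
  ```

  with a temporal-smoothness penalty (α₁ = 0.04, variant 0.004) and a
  spatial total-variation penalty (α₂ = 0.006), 1000 iterations, complex
  result combined as √(Re² + Im²).

* **Non-iterative FBP** (`fbp_reconstruct()`, `run_version()`): missing
  views are synthesised from measured neighbours by a monotone
  deformation-field matcher on the sinogram (`extend_views()`), each line is
  filtered with the regularised ramp `H(ω) = |ω| / (1 + β|ω|)`, inverse
  transformed, and backprojected; versions V1 (24→72 extended), V2/V3 (raw
  24 views) and V4 (fully sampled gold standard) mirror the standard
  comparison layout.

* **Evaluation** (`run_comparison()`, `metrics_table()`): every magnitude
  series is 3×3 median filtered and scored against the V4 gold standard by
  pooled RMSE and SSIM, emitting the per-dataset method tables.

The headline observation the package reproduces mechanistically: the
temporal constraint that makes iterative reconstructions look less noisy
*biases* fast-changing signal — on a noiseless step-change phantom the
reconstructed enhancement step shrinks as α₁ grows.

## Worked example

```r
library(radialrecon)

spec <- phantom_spec()            # 128x128, 20 frames, SNR~10 gold standard
cmp  <- run_comparison(spec, seeds = 1, alpha1 = 0.04, n_iter = 1000)
metrics_table(cmp, "rmse")
#> # A tibble: 1 x 5
#>   dataset `gold (beta=0)` `raw (beta=0)` `extended (beta=1)` `bayes (alpha1=0.04)`
#>     <dbl>           <dbl>          <dbl>               <dbl>                 <dbl>
#> 1       1               0         0.0994              0.0658                0.0950
```

Reading the row: the gold standard scores 0 against itself by construction;
the raw 24-view ramp reconstruction is the worst method (streaks plus
unfiltered noise); extending 24 → 72 views before FBP cuts the error by a
third; the iterative method lands between them. `metrics_table(cmp, "ssim")`
gives the SSIM counterpart (gold exactly 1, higher is better), and
`autoplot(cmp, "rmse")` draws the comparison. `autoplot()` on any
`dynamic_series` shows frame montages; `write_series_nifti()` /
`write_metrics_csv()` / `write_phantom_spec()` export series, tables and
configurations.

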