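---
title: "Sparse-view dynamic MRI: iterative versus non-iterative reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-view dynamic MRI: iterative versus non-iterative reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radialrecon)
```

# The problem

Dynamic contrast-enhanced MRI must trade temporal resolution against angular
sampling: acquiring only 24 radial k-space views per frame instead of the 72
needed for an alias-free image shortens each frame's readout threefold, but
conventional reconstruction of such sparse-view data is dominated by streak
artifacts and noise. `radialrecon` implements and compares the two standard
answers on a synthetic dynamic phantom with known ground truth:

* an **iterative Bayesian reconstruction** that minimises a data-fidelity
  term plus a temporal-smoothness penalty and a spatial total-variation (TV)
  penalty over the whole image series jointly, and
* a **non-iterative filtered backprojection (FBP)** whose missing view
  angles are first synthesised from the measured ones by a deformation-based
  sinogram interpolation, and whose ramp filter carries a minimum-norm
  regularisation `|ω| / (1 + β|ω|)`.

The comparison protocol scores every method, after 3×3 median filtering,
against the fully sampled 72-view ramp FBP ("gold standard") by RMSE and
SSIM. The scientific point is not that one method wins outright but that the
temporal constraint of the iterative method *biases* fast-changing signal:
a Bayesian prior that makes images look better can move their values.

# The iterative model

For complex frames $m_t$ on an $N\times N$ grid, gridded sparse k-space data
$d_t$ and binary sampling masks $W_t$, the objective is

$$C = \sum_t \lVert W_t \circ F m_t - d_t \rVert_2^2
  + \alpha_1 \sum_{t,i} \lvert \nabla_t m_{t,i} \rvert^2
  + \alpha_2 \sum_{t,j} \sqrt{\lvert\nabla_x m_{t,j}\rvert^2 +
      \lvert\nabla_y m_{t,j}\rvert^2 + \varepsilon}.$$

All differences are forward differences with a zero (Neumann) difference at
the last sample of each axis; the TV magnitude couples the real and
imaginary channels through one shared denominator. The final image is the
elementwise norm $\sqrt{m_\mathrm{real}^2 + m_\mathrm{imag}^2}$
(`combine_norm()`).

**Fourier normalisation.** The model statement leaves the DFT normalisation
open, but the choice matters: with an unnormalised DFT the fidelity Hessian
bound is $2N^2$, and a stable gradient step is so small that
$\alpha_1 = 0.04$, $\alpha_2 = 0.006$ never act within the iteration budget.
We therefore use the *orthonormal* convention — equivalently, fidelity is
$\lVert W \circ (Fm - d)\rVert^2 / N^2$ with $d$ in plain DFT units — under
which fidelity, temporal and TV terms all live on the image scale and the
standard weights are meaningful regardless of grid size.

**Optimisation.** `reconstruct()` starts from the zero-filled inverse
transform $F^{-1} d_t$ and runs plain fixed-step gradient descent, jointly
over all frames, with step $1/L$ where $L$ is a power-iteration estimate of
the fidelity Hessian bound (exactly 2 in the orthonormal convention). The
smoothed TV term has curvature $\sim \alpha_2/\sqrt{\varepsilon}$ wherever a
local gradient magnitude dips below $\sqrt{\varepsilon}$; enforcing strict
per-iteration monotonicity against those isolated spikes would clamp the
step about fifty-fold and leave the temporal term largely unapplied after
1000 iterations, so the monotone variant (`backtracking = TRUE`, with step
halving and geometric recovery) is provided as an option and verified in the
tests, while the default reproduces the reference algorithm's fixed-step
behaviour and lets isolated pixels chatter harmlessly.

Defaults (`bayes_config()`): $\alpha_1 = 0.04$ (variant $0.004$),
$\alpha_2 = 0.006$, $\varepsilon = 10^{-8}$, 1000 iterations.

# The non-iterative pipeline

`fbp_reconstruct()` runs, per frame: optional view extension → line-by-line
filtering → per-line 1D inverse Fourier transform → pixel-driven
backprojection of the real and imaginary channels separately → elementwise
norm. Four versions are exposed through `run_version()`: V1 (24 views
extended to 72, regularised ramp), V2 (raw 24 views, regularised ramp), V3
(raw 24 views, plain ramp) and V4 (72 measured views, plain ramp — the gold
standard).

**Units of β.** The ramp magnitude is applied in frequency-index units (so
the backprojection quadrature reconstructs true amplitudes), but the
regularising rolloff $1/(1+\beta\lvert\omega\rvert)$ is evaluated on the
cycles-per-sample axis $\lvert\omega\rvert \le 1/2$. On that axis
$\beta = 1$ attenuates the Nyquist gain by $1.5\times$ and $\beta = 2$ by
$2\times$ — the moderate-denoising regime; had β acted on the index axis
$[0, N/2]$, $\beta = 1$ would flatten the ramp entirely and blur every
sparse reconstruction beyond use.

**DC-cell quadrature.** The frequency integral behind FBP is evaluated as a
Riemann sum over unit frequency cells. $H$ is smooth within every cell
except the one containing the kink at $\omega = 0$; there the exact cell
average ($1/4$ for the plain ramp) replaces the point value $0$. Without
this the reconstruction loses a constant near 18 % of the object mean — the
classic DC offset of naively sampled ramp filters. The transfer function
itself (`filter_transfer()`, `filter_lines()`) still gains 0 at the DC
sample.

# Deformation-based view extension

Between two angularly adjacent measured lines $L_1$ and $L_4$,
`estimate_deformation()` finds, per sample of $L_1$, a corresponding sample
of $L_4$: the monotone non-decreasing map $j(i)$ with pinned endpoints and a
pinned DC centre that minimises

$$\sum_i \left(\lvert L_1[i]\rvert - \lvert L_4[j(i)]\rvert\right)^2
  + \lambda \sum_i (j(i) - i)^2,$$

solved exactly by dynamic programming, with ties broken towards the
identity. The proximity term expresses that adjacent views see nearly the
same radial profile, so the correspondence should be a *small* deformation:
without it the matcher is free to ride the oscillations of the k-space
magnitude profile and wander ±8 samples even between near-identical lines,
which ruins the interpolation. The default
$\lambda = 0.1 \cdot \operatorname{mean}\left(\left(\lvert L_1\rvert - \lvert L_4\rvert\right)^2\right)$
is scale invariant, vanishes for identical lines (restoring the exact
tie-break to identity) and leaves genuine shifts detectable.

`synthesize_intermediate()` treats each correspondence as a segment in polar
coordinates from $(r_i, \theta_1)$ to $(r_{j(i)}, \theta_4)$: the crossing
with the target angle interpolates both the radius and the complex value
linearly in angle, and the scattered radius–value pairs are resampled onto
the uniform radial grid. With this reading, radially consistent data are a
fixed point of the synthesis to machine precision — a property a straight
Cartesian chord would violate, because a constant-radius correspondence
would then cross the target ray at a strictly smaller radius.
`extend_views()` triples the view count (two synthesised lines per gap),
carries measured lines over bit-exactly, and bridges the wraparound gap by
pairing the last line with the radially *reversed* first line — the exact
half-turn identity $S(r, \theta + 180^\circ) = S(-r, \theta)$, valid for any
complex image (a conjugated reversal would additionally assume a real
image).

# The synthetic study

`phantom_spec()` describes a first-pass perfusion scene: a static body disk,
a "myocardium" ellipse and a "ventricle" ellipse whose intensities follow
gamma-variate enhancement curves
$g(t) = A\,(\tau/\alpha\beta)^\alpha e^{\alpha - \tau/\beta}$,
$\tau = t - t_0$ — the standard parametric bolus model, rising from 0 at
$t_0$ and peaking at exactly $A$ at $t_0 + \alpha\beta$. A fixed low-order
polynomial phase map makes the object genuinely complex, so the
separate-channel processing of both reconstructions is exercised
nontrivially. Acquisition (`simulate_acquisition()`) evaluates the exact
discrete-space Fourier transform along each view (central-slice theorem, a
separable matrix-product evaluation checked against a brute-force
nonuniform DFT) and adds i.i.d. complex Gaussian noise in k-space.

Chosen study conditions, fixed in the generator defaults:

* **Geometry**: 72 uniform views over 180°, threefold undersampling to 24
  views, samples per line equal to the grid size. Desk scale is
  128 × 128 × 20 frames (the full-scale 256 × 256 × 75 geometry is one
  argument away but not the default).
* **Interleaving**: frame $t$ keeps views congruent to $t \bmod 3$, so three
  consecutive frames jointly cover all 72 angles. This is the regime in
  which a temporal constraint can recover a frame's unmeasured views from
  its neighbours — with a frame-constant pattern it could only average
  re-measured cells and its characteristic bias could never arise.
* **Noise**: $\sigma = 15$ per complex k-space sample, calibrated so the
  gold-standard reconstruction has SNR ≈ 10 at peak myocardial
  enhancement — the noisy single-coil regime in which sparse ramp
  reconstructions are visibly streak- and noise-limited.
* **Dynamics**: LV bolus amplitude $A = 3$ (severalfold enhancement over
  baseline, as in first-pass imaging), myocardium $A = 0.8$.

What the generator does *not* emulate: anatomy (concentric ellipses, not
hearts), motion (no respiratory or cardiac displacement), coil sensitivity
profiles, gradient-system imperfections, or the unknown intensity scale of
scanner units. Passing orderings on this phantom therefore demonstrate the
mechanisms — streak reduction by view synthesis, denoising and bias by the
temporal prior — not clinical performance.

# Evaluation protocol

`run_comparison()` runs every method per seed and scores median-filtered
magnitudes against the median-filtered gold standard: pooled RMSE over all
pixels and frames, and SSIM (11 × 11 Gaussian window, σ = 1.5,
$K_1 = 0.01$, $K_2 = 0.03$, dynamic range = max − min of the gold series,
averaged over frames). The median window (3 × 3, mirrored borders) is the
smallest standard denoiser; the kernel size is a parameter. RMSE is pooled
rather than per-frame-averaged, matching one number per dataset per method.

```{r example, eval = FALSE}
cmp <- run_comparison(phantom_spec(), seeds = 1:3,
                      alpha1 = c(0.04, 0.004), n_iter = 1000)
metrics_table(cmp, "rmse")
autoplot(cmp, "rmse")
```

# Findings on the synthetic study, and a caveat

At the frozen study conditions the synthetic tables reproduce the central
orderings: raw 24-view FBP is the worst method on every dataset; extending
24 → 72 views before FBP beats both the raw reconstruction and the
iterative method; increasing β reduces flat-region noise monotonically.

The temporal-bias mechanism is demonstrated directly: on a noiseless
step-change phantom the reconstructed step height is underestimated
strictly more at $\alpha_1 = 0.04$ than at $0.004$ (the tests assert the
direction on the step *height*, where static reconstruction systematics
cancel — the raw region-mean error is confounded by a ~1.6 % FBP/gridding
offset that the downward bias first cancels).

One reported effect does **not** transfer to this phantom: reducing
$\alpha_1$ from 0.04 to 0.004 does not reduce the pooled RMSE here (it
increases it by ~0.7 %). Pooled RMSE trades the temporal term's variance
reduction, which benefits every pixel of the series, against its dynamics
bias, which is confined to the fast-enhancing ventricle — about 4 % of this
phantom's field of view over a handful of frames. Patient data, whose
enhancing blood pools fill much of a cardiac field of view, sit on the other
side of that tradeoff. We keep the phantom as designed rather than reshaping
it around the expected outcome, and read the discrepancy as informative: the
sign of the α₁ effect on a pooled error is a property of the scene, not of
the algorithm.

# Numerical choices

* Centred FFT bookkeeping (DC at index $n/2$, 0-based) is shared by all
  modules through one helper pair; for even sizes it is implemented as a
  checkerboard modulation rather than explicit shifts.
* Gridding scatters each radial sample bilinearly onto its 4 neighbouring
  Cartesian cells with weight normalisation; a cell is "measured" above a
  total weight of $10^{-8}$. No density compensation — the fidelity term
  compares masked coefficients directly, and the FBP path never grids.
* Backprojection interpolates projections linearly and scales by
  $\pi/n_\mathrm{views}$; `project_image()` is its exact adjoint.
* Degenerate inputs: zero k-space reconstructs to zero; a constant SSIM
  reference substitutes dynamic range 1; divergence of the descent
  (non-finite objective) raises an error naming the iteration.
* Problem sizes in the test suite: oracles run at 8–16 pixels, property
  checks at 32–64, the study-scale checks at the default 128 × 128 × 20
  with 1000 iterations and three seeds.

# Limitations

* The deformation matcher is a deterministic stand-in built from the
  properties the method's description fixes (monotone, non-iterative,
  close corresponding values); the original reference's exact estimator is
  not public.
* Interpolation-based view synthesis assumes the object is angularly smooth
  between adjacent measured views; rapidly rotating features would violate
  this.
* The iterative method's runtime (~35 s per 1000 iterations at desk scale)
  and the FBP's (~0.3 s per frame) differ by the two orders of magnitude
  the non-iterative method is meant to save.
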