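---
title: "Methods: polarimetric processing, diffusion denoising, and the synthetic phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polarimetric processing, diffusion denoising, and the synthetic phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(muellerpol)
```

# The imaging model

Wide-field imaging Mueller polarimetry probes a sample with four
polarisation states and analyses the back-scattered light in four states,
so each pixel yields a 4x4 tensor of real intensities `I`. With the
calibrated polarisation state generator `G` and analyser `A` (4x4 each,
global or per pixel), the tissue's Mueller matrix per pixel is

    M = A^-1 I G^-1 ,

and the forward map used by the simulator is `I = A M G`. `muellerpol`
stores an acquisition as an H x W x 16 channels-last tensor whose channel
order is row-major over (generator, analyser) pairs; `state_channel(g, a)`
is the single place where that convention is defined and it is asserted in
the unit tests. The inversion is computed as a closed-form cofactor
(adjugate) expansion vectorised over all pixels -- a whole frame is one
batched pass of constant-size 4x4 algebra, with a generic per-pixel
`solve()` loop kept in the test suite as the independent oracle.
Calibration blocks are screened by their Frobenius condition number
(default bound 1e8); singular generators or analysers are a hard error
naming the offending matrix or pixel.

# Lu-Chipman decomposition and the scalar maps

Each (M11-normalised) Mueller matrix is factorised as the product
`M = M_Delta M_R M_D` of a depolariser, a retarder and a diattenuator, in
the classical polar-decomposition order: the diattenuation vector is read
off the first row of `M`, `M_D` is built from it analytically, and
`M' = M M_D^-1` is split by taking the depolariser submatrix as the signed
symmetric eigen-square-root of `m' m'^T` (sign from `det m'`), the
retarder being what remains. Pixels where the factorisation is impossible
(diattenuation >= 1 from noise, negative eigenvalues beyond tolerance,
non-finite input) are flagged in a validity mask and never thrown:
full-frame processing must survive noisy background.

The four scalar maps are

* total diattenuation `D = sqrt(M_D12^2 + M_D13^2 + M_D14^2)`,
* total depolarisation `Delta = 1 - |tr(m_Delta)|/3` over the 3x3
  depolariser submatrix,
* scalar retardance
  `R = acos( sqrt((M_R22 + M_R33)^2 + (M_R32 - M_R23)^2) - 1 )`
  with the inner argument clamped to [-1, 1], reported in degrees,
* optical-axis azimuth `phi = 1/2 * atan2(-M_R24, -M_R43)`, wrapped onto
  the axial interval [0, 180) degrees.

Two conventions deserve a note. First, the depolarisation trace is taken
over the 3x3 submatrix: including the (1,1) = 1 element in a 4x4 trace
would break the guarantee `Delta` is in [0, 1]; the literal 4x4 variant
remains available via `scalar_params(..., delta_trace = "full4")` for
comparison. Second, the azimuth uses a quadrant-aware two-argument
arctangent rather than the plain ratio `M_R24 / M_R43`, which is
90-degree ambiguous; the sign convention is pinned by the quarter-wave
plate form of `make_linear_retarder(0, 90)` and chosen so that
`scalar_params(decompose(make_linear_retarder(theta, delta)))` returns
exactly `R = delta`, `phi = theta` -- a property the test suite checks on
a dense grid to 1e-6 degrees. The azimuth is additionally flagged
low-confidence wherever `sin(R)` is approximately 0, where it is
mathematically undefined.

# The synthetic phantom

No clinical acquisitions ship with the package; a synthetic brain-tissue
phantom (`phantom_spec()` / `make_phantom()`) provides inputs with exact
ground truth. It emulates, per pixel,

1. a tissue-class map (background, grey matter, white matter, tumour
   centre, tumour infiltration) drawn as thresholded smoothed noise blobs
   plus a lesion disk with an infiltration ring;
2. a fibre-orientation field: a smooth low-frequency flow followed by
   white matter; grey matter and the infiltration ring add *spatially
   correlated* angular dispersion (unit-variance smoothed noise fields
   scaled to 25 and 50 degrees respectively, correlation length
   `0.05 * h`); the tumour centre is uniformly random per pixel, i.e.
   fully disrupted;
3. ground-truth Mueller matrices
   `M = M_Delta(class) . LR(theta, delta(class)) . M_D(class)` with the
   diattenuation axis aligned to the fibre axis;
4. forward imaging `I = A M G` through randomly perturbed calibration
   matrices (condition number < 10, so the inversion is exercised
   nontrivially);
5. pseudo-Gaussian acquisition noise added in the intensity domain, and
   n-shot averages for n = 1 (LQ), 8 (HQ) and 16 (SHQ).

Default per-class optics (all configurable, chosen to reproduce the
qualitative contrasts of polarimetric brain imaging -- strong coherent
retardance in white matter, weaker in grey matter, depolarising
disorganised lesion core): white matter `delta` = 40 deg, depolariser
diagonal (0.85, 0.85, 0.80), diattenuation 0.05; grey matter 10 deg,
(0.70, 0.70, 0.65), 0.03; tumour centre 8 deg, (0.60, 0.60, 0.55), 0.03;
infiltration intermediate (24 deg, (0.72, 0.72, 0.67), 0.04); background
is a near-total depolariser and is excluded from every ROI.

The noise is a zero-mean Gaussian scale mixture: with probability
`1 - kappa` a draw from `N(0, sigma^2)`, with probability `kappa` from
`N(0, (w sigma)^2)`. This is "pseudo-Gaussian" in the intended sense --
symmetric, bell-shaped, with a cumulative distribution deviating slightly
from the normal reference (positive excess kurtosis
`3(1-k+k w^4)/(1-k+k w^2)^2 - 3`). Defaults `sigma = 0.08` (in
M11-normalised intensity units), `kappa = 0.05`, `w = 3`. The core width
was set so that the single-shot regime is *noise-dominated* in the derived
azimuth (circular RMSE of 12-18 degrees against truth at 64x64), because
that is the regime the study design describes: oriented white-matter
patterns in the azimuth map emerge only after denoising or multi-shot
averaging. The angular dispersion in grey matter and infiltration is
spatially correlated rather than pixel-iid on purpose: fibre fanning has
spatial extent, and a reference field that is white at the pixel scale
could not be recovered by any spatial method, making comparisons between
denoisers meaningless.

What the phantom does **not** emulate: optical scattering and photon
transport, specular reflections (beyond a maskable option), wavelength
dependence, motion or bleeding artefacts, and co-registration error
between quality levels. Passing tests on the phantom therefore shows the
*processing chain* is correct and that denoising recovers structure under
the stated noise model -- not that any particular clinical effect size
would be reproduced on real acquisitions.

# The denoising diffusion model

The denoiser treats a single-shot acquisition as an intermediate state of
a forward diffusion. With a linear variance schedule `beta_t` over `T`
time-points (`T = 1000` at full scale; endpoints 1e-4 to 0.02, the
canonical choice -- the source design leaves the shape unspecified), the
corrupted state has the closed-form marginal

    x_t = sqrt(abar_t) x_0 + sqrt(1 - abar_t) eps,   eps ~ N(0, J),

with `abar_t` the cumulative product of `1 - beta_t`. A U-Net is trained
self-supervised on high-quality (multi-shot averaged) frames only: draw a
patch `x_0` scaled to [-1, 1], a uniform time-point and a noise tensor,
and regress `eps` under an L1 loss with Adam. Reflection-masked pixels
are excluded from the loss; augmentation is random 90-degree rotation,
flips, and random cropping (with mirror padding when a frame is smaller
than the patch).

The network is the standard diffusion U-Net, built here from first
principles (no deep-learning framework is involved): wide residual
blocks of group normalisation, SiLU and 3x3 convolutions with a learned
per-block time-embedding bias, 2x2 average pooling and nearest
upsampling between resolution levels with channel multipliers
(1, 2, 4, 8) at full scale, encoder-decoder skip concatenations,
single-head self-attention at the coarsest resolutions, and a
zero-initialised output convolution. Every layer's backward pass is
hand-written and verified against finite differences in the test suite
(worst relative error below 1e-4 across all parameter tensors). The
forward pass is expressed as a flat op-tape executed by a stack machine;
the backward pass walks the same tape in reverse, so the two cannot
drift apart.

**Single-pass inference.** At inference the noisy frame (rescaled to
[-1, 1] with the bounds recorded at training) is treated as the state at
a terminal time-point `t*` and one reverse posterior-mean step is taken
in x0-form: `x0_hat = (x - sqrt(1 - abar_t*) eps_hat) / sqrt(abar_t*)`,
clipped to [-1, 1], no noise injection. `t* = 1` is the strict reading;
the pipeline default is noise-matched selection: the per-frame noise
level is estimated with Immerkaer's Laplacian estimator and `t*` chosen
so that `sqrt(1 - abar_t*)` matches it. Both are exposed
(`denoise_single_pass(..., t_star =)`, `denoise_frame(..., t_star =)`).
Full frames are processed by overlapped tiling with a strictly positive
cosine blending window; because self-attention is global within a tile,
tiling is only approximately local, and the tests bound the interior
discrepancy rather than asserting exact equality.

**Desk-scale preset.** Training the full-scale configuration is a
GPU-days task. The package ships a `"desk"` preset sized for a single
CPU: `T = 200`, 32x32 patches, width 12 with multipliers (1, 2, 4),
attention at the coarsest level, batch 4, 2500 steps with cosine
learning-rate decay from 1e-3 and an exponential moving average of the
weights (decay 0.999 with warm-up) used at inference. One training run
takes a few minutes and measurably denoises the phantom; it is a
miniature of the method, not a reproduction of the published model's
capacity. All experiment sizes quoted in this vignette (64x64 phantom
frames, three training phantoms, 2500 steps) are the package's chosen
desk-scale study conditions.

**Baselines.** Deterministic channel-wise filters for comparison: 3x3
median (`MEDF`), normalised 5x5 Gaussian kernel (`GBLR`, unit DC gain),
and Perona-Malik gradient anisotropic diffusion (`GRAD`, 5 iterations,
conductance 1, time step 0.125). They are implemented on the package's
own replicate-padded convolution core so the kernels match their stated
definitions exactly.

# Evaluation

Quantities with axial support (azimuth, and retardance treated as
angular) use circular statistics throughout, via the angle-doubling
transform: differences are wrapped into (-90, 90] degrees before
squaring (`rmse(..., circular = TRUE)`), and the local orientation
dispersion map `csd_map()` doubles the angles in each (default 5x5)
neighbourhood, computes the mean resultant length `Rbar` over valid
neighbours, and reports `csd = 1/2 sqrt(-2 ln Rbar)` in degrees, capped
at a configurable maximum (default 1e3 degrees) where the resultant
vanishes, with fewer than 3 valid neighbours yielding `NA`.

`npsnr()` is `20 log10(range / RMSE)` with the peak taken as the
reference's dynamic range inside the ROI (axial quantities use the fixed
180-degree range); normalising by the reference range keeps the score
comparable across quantities with different units, and the choice is
recorded in the report. `ssim()` is the standard windowed structural
similarity (7x7 Gaussian window, sigma 1.5, k1 = 0.01, k2 = 0.03),
reported in percent. Score samples are summarised as q1/median/q3
quartiles (linear interpolation between order statistics) per quantity
and method, with two-sided Wilcoxon rank-sum tests against a designated
reference method; the exact rank-sum distribution is enumerated by
dynamic programming over doubled midranks for combined samples up to 20
(correct under ties), larger samples use the normal approximation with
tie correction.

# Numerical choices and edge cases

* Mueller blocks with `|M11| <= eps` (default 1e-12) cannot be
  normalised and are flagged invalid, values untouched.
* The eigen-square-root clamps eigenvalues in `(-1e-9, 0)` to zero;
  more negative values mark the pixel invalid.
* The retardance arccos argument is clamped to [-1, 1] so noise cannot
  produce NaN.
* The azimuth is reported on [0, 180) and flagged undefined where
  `sin(R)` is approximately 0.
* `csd_map`'s resultant length is snapped to 1 within 1e-12 so constant
  fields give exactly zero dispersion.
* All randomness (phantom, training, augmentation) flows from a single
  top-level seed fanned out to per-stage child seeds, so every pipeline
  product is bit-reproducible from its configuration document.

# Known limitations

* The desk-scale denoiser is far below the published model's capacity;
  it demonstrates and tests the method's mechanics, and its improvements
  over the single-shot branch are real but modest (it does not reach
  multi-shot-average quality).
* Tiled full-frame inference is approximate near tile boundaries when
  attention is enabled (bounded, tested, but not exact).
* The phantom's noise is white across pixels and channels; real sensor
  noise may be correlated and exposure-dependent.
* Physical admissibility of noisy Mueller matrices is handled by
  masking, not by projection onto the physical cone.
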