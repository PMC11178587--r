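# muellerpol

Mueller polarimetric image processing for tissue imaging, with
diffusion-based denoising of single-shot acquisitions.

Wide-field imaging Mueller polarimetry measures how a sample transforms
polarised light: 16 intensity images, one per (generator, analyser)
polarisation-state pair, determine each pixel's 4x4 Mueller matrix via

    M = A^-1 I G^-1

where `G` and `A` are the instrument's calibration matrices. The
Lu-Chipman polar decomposition `M = M_Delta M_R M_D` then yields the
clinically interpretable scalar maps: total diattenuation
`D = sqrt(M_D12^2 + M_D13^2 + M_D14^2)`, total depolarisation
`Delta = 1 - |tr(m_Delta)|/3`, scalar retardance
`R = acos(sqrt((M_R22+M_R33)^2 + (M_R32-M_R23)^2) - 1)`, and the
optical-axis azimuth `phi = 1/2 arctan(M_R24 / M_R43)` (computed
quadrant-aware). In brain tissue the azimuth tracks white-matter fibre
orientation, and its local circular standard deviation `csd(phi)`
separates coherent tracts (low) from disrupted tumour tissue (high).

High-quality parameter maps conventionally require averaging many camera
shots, which is incompatible with real-time use. This package implements
a denoising diffusion probabilistic model for 16-channel polarimetric
intensities: an epsilon-prediction U-Net trained self-supervised on
high-quality frames only, applied to a single noisy shot as one reverse
posterior-mean step at a noise-matched time-point. Classical baselines
(3x3 median, 5x5 Gaussian blur, Perona-Malik anisotropic diffusion),
circular-statistics evaluation (RMSE/nPSNR/SSIM, csd maps, rank-sum
tests) and a synthetic brain-tissue phantom with exact ground truth
complete the toolkit. The audience is researchers in tissue polarimetry
and computational imaging who need a fully inspectable, dependency-light
reference implementation.

## Worked example

```r
library(muellerpol)

# A 64x64 synthetic brain-tissue acquisition: tissue classes, fibre
# orientation field, 16 noisy shots, and exact ground truth.
ph <- make_phantom(phantom_spec(h = 64, w = 64, seed = 42))
ph
#> <acquisition_set 64 x 64, 16 shots, sigma = 0.08>
#>          background         grey_matter        white_matter
#>                 615                1669                1461
#>       tumour_centre tumour_infiltration
#>                 127                 224

# Single-shot (LQ) branch: derive Mueller matrices and scalar maps.
M  <- normalise_m11(derive_mueller(ph$averaged[["1"]], ph$calib))
pm <- scalar_params(decompose(M))
pm
#> <parameter_maps 64 x 64, 4096 valid px>
#>   D     median 0.1145  [0.006127, 0.7006]
#>   Delta median 0.267  [-0.6614, 0.9497]
#>   R     median 29.28  [0.6547, 176.9]
#>   phi   median 48.04  [0.1077, 180]

# Azimuth error of the noisy branch vs ground truth, in degrees:
roi <- ph$roi & pm$valid & ph$gt_params$phi_defined
rmse(pm$phi, ph$gt_params$phi, roi, circular = TRUE)
#> [1] 14.24513

# Gaussian-blur baseline improves it:
Mb  <- normalise_m11(derive_mueller(baseline_filter(ph$averaged[["1"]],
                                                    "GBLR"), ph$calib))
pmb <- scalar_params(decompose(Mb))
rmse(pmb$phi, ph$gt_params$phi, roi & pmb$valid, circular = TRUE)
#> [1] 10.96786

# Train the desk-scale diffusion denoiser on high-quality (8-shot) frames
# (a few minutes on one CPU), then denoise the single shot:
hq <- lapply(1:3, function(s)
  unclass(make_phantom(phantom_spec(h = 64, w = 64,
                                    seed = 100 + s))$averaged[["8"]]))
b  <- list(min = min(sapply(hq, min)), max = max(sapply(hq, max)))
hq <- lapply(hq, function(f) rescale_unit(f, b)$x)
model <- train_pddn(hq, pddn_preset("desk"), seed = 7, bounds = b)
den <- denoise_frame(ph$averaged[["1"]], model)
pmd <- scalar_params(decompose(normalise_m11(derive_mueller(den, ph$calib))))
rmse(pmd$phi, ph$gt_params$phi, roi & pmd$valid, circular = TRUE)
#> [1] 11.00481
```

The numbers above are what the code printed for seed 42: single-shot
azimuth error of 14.2 degrees drops to about 11 degrees for both the blur
baseline and the single-pass diffusion denoiser, and the phantom's median
depolarisation in tissue (~0.27) and retardance (~29 deg) reflect the
configured white/grey-matter optics. On noisy frames the decomposition is
computed everywhere it is numerically possible, so background pixels can
carry out-of-range depolarisation values; ROI masks confine analysis to
tissue. `run_pipeline()` chains all stages from a YAML configuration,
and `exec/muellerpol` exposes the subcommands `phantom`, `derive`,
`decompose`, `train`, `denoise`, `evaluate`, `pipeline`.

## Layout

* `R/mueller_core.R`, `R/lu_chipman.R`, `R/elements.R` — polarimetric
  algebra (batched closed-form 4x4 solves, polar decomposition, analytic
  optical elements).
* `R/phantom.R` — the synthetic acquisition generator.
* `R/schedule.R`, `R/nn.R`, `R/unet.R`, `R/train.R`, `R/denoise.R` — the
  diffusion denoiser (hand-rolled U-Net with verified backprop) and
  baseline filters.
* `R/evaluation.R` — circular statistics and image-quality scores.
* `R/io_stack.R`, `R/pipeline.R`, `exec/muellerpol` — file formats,
  configuration, end-to-end pipeline and CLI.
* `vignettes/muellerpol-methods.Rmd` — model assumptions, parameter
  choices, numerical edge cases, limitations.
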