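Package: muellerpol
Title: Mueller Polarimetric Image Processing with Diffusion-Based Denoising
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end processing of wide-field imaging Mueller polarimetry
    acquisitions: derivation of per-pixel Mueller matrices from 16-state
    polarimetric intensity tensors, Lu-Chipman polar decomposition into
    diattenuation, retardance, depolarisation and optical-axis azimuth maps,
    a denoising diffusion probabilistic model for single-shot low-quality
    acquisitions together with classical denoising baselines, circular
    statistics for axial orientation data, and a synthetic brain-tissue
    phantom generator for validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
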