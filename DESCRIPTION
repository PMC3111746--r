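Package: dwiqc
Title: Slicewise Quality Control and Tensor Fitting for Diffusion-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Automated detection of motion-induced slice-dropout artifacts in
    diffusion-weighted MRI. For every axial slice of every diffusion-weighted
    volume a relative intensity deviation against the same slice in all other
    volumes is computed, weighted by gradient-direction similarity (the dot
    product of the encoding directions), and volumes whose deviation exceeds a
    threshold are excluded before tensor fitting. Also provides log-linear
    least-squares diffusion tensor estimation, fractional anisotropy (FA)
    mapping with masked Gaussian smoothing, with/without-QC FA comparison,
    a synthetic single-shell phantom simulator with Rician noise and
    ground-truth labelled slice dropouts, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    withr,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
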