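Package: lair
Title: Limited-Angle Iterative Reconstruction for Micro-CT with Sinogram Inpainting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying limited-angle (LA) micro-CT reconstruction on the
    desktop: Monte-Carlo phantom and sinogram simulation, a Siddon ray-driven
    fan/parallel-beam projector with an exact sparse system matrix, filtered
    backprojection, TV-constrained iterative reconstruction (EM-TV and ASD-POCS)
    driven by an image-quality-based stopping criterion, a context-encoder
    adversarial network that inpaints the missing angular band of an LA sinogram,
    and the full set of figure-of-merit computations (PSNR, UIQI, SSIM, rTV, CNR,
    SNR, Gaussian-fit FWHM and ROI linearity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
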