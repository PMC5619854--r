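Package: icebg
Title: Global Background Modelling for X-Ray Diffraction Images with Ice Rings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a static per-pixel background model for rotation-series
    X-ray diffraction data contaminated by water ice rings. The model is the
    masked mean image of the stack, regridded onto a polar (resolution by
    azimuth) grid by count-conserving polygon clipping, cleaned by a wrapped
    median filter along lines of constant resolution, completed by iterative
    Laplace diffusion over masked cells, and regridded back to the detector.
    The model is then fitted to each reflection's background pixels by Poisson
    maximum likelihood, with a robust variant using the Anscombe
    variance-stabilising transform and Huber-weighted iteratively reweighted
    least squares, and reflections are integrated by summation. A simulator
    with known ground truth (Poisson counts, smooth radial background, sharp
    and diffuse ice rings, Gaussian Bragg spots) and diagnostic summaries
    (index-of-dispersion images, intensity versus resolution, fourth moments
    of normalised structure factors) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
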