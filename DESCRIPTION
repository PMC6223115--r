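Package: spinedyn
Title: Stochastic Drift-Diffusion Modelling of Dendritic Spine Volume Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the in vivo volume dynamics of dendritic
    spines as a one-dimensional Ito diffusion on spine-head volume. Implements
    binned moment estimation of the drift and fluctuation laws from
    longitudinal two-photon volume tables, decomposition of total fluctuations
    into fast (minute-scale) and slow (day-scale) components, surface-area
    (V^(2/3)) scaled anchored slope fits, Fokker-Planck stationary volume
    distributions with reflecting boundaries, spine elimination rates under an
    absorbing boundary at the minimal volume, Euler-Maruyama simulation of the
    Langevin dynamics, fluorescence-to-volume calibration via a point-spread
    function convolved sphere model, and a synthetic cohort generator for
    end-to-end validation without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    pracma,
    ggplot2,
    optparse,
    tiff,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
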