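Package: mesosim
Title: Stochastic Reaction-Diffusion Simulation with Concentration-Dependent
    Mesoscopic Rate Constants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatial stochastic simulation of reaction-diffusion systems on 2D
    periodic domains with the Next Subvolume Method, using scale-dependent (k_h)
    and concentration-dependent (k_c) mesoscopic bimolecular rate constants
    derived from microscopic (Smoluchowski / lambda-rho) parameters. Includes a
    Brownian-dynamics particle engine as microscopic ground truth, a stochastic
    model of Cdc42 polarity establishment in budding yeast with all macroscopic /
    2D / 3D parameter conversions, and spatial point-pattern and cluster-mobility
    statistics: Besag-L-type H(r) clustering, toroidal centroid tracking, mean
    squared displacement and patch diffusivity fitting, coefficient of spatial
    variation, and tagged-species dwell times.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(load = "installed")
RoxygenNote: 7.3.3
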