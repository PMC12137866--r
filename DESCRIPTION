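Package: leapscan
Title: Interleaved Scan Patterns, Charging Simulation and Image QC for Cryo-SEM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for engineering scanning electron microscopy (SEM) acquisition
    strategies on charge-prone (insulating) specimens such as vitrified biological
    samples. Generates timed raster and interleaved ("leapfrog") scan patterns with
    line or frame integration and exports them as coordinate text files for
    programmable scan engines; simulates charge deposition, isotropic lateral
    dissipation and charge-dependent secondary-electron detection on synthetic
    specimen phantoms (lipid droplets, myelin stacks, membranes); and provides the
    quantitative image-quality pipeline used to compare strategies: 8-bit
    conversion, flyback-distortion estimation and cropping, patch-based frame
    alignment and integration, histogram charging metrics, segmentation complexity
    scoring, streak-anisotropy, quadrant count ratio and condition comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
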