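Package: vesselquant
Title: Label-Free Vascular Phenotyping of Zebrafish Trunk Vasculature from
    Phase-Difference OCT Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify tumor-associated angiogenesis in the zebrafish
    trunk from optical coherence tomography angiography (OCTA) and GFP
    fluorescence en-face maps. Provides a parametric generator of synthetic
    trunk vasculature (healthy and hyperbranched RAS+ phenotypes) with exact
    geometric ground truth, a complex-valued BM-scan OCT simulator with
    closed-form Doppler phase, phase-difference angiogram reconstruction with
    bulk-motion removal and en-face projection, OCTA-fluorescence fusion with
    structural similarity (SSIM) scoring, five topological vessel-network
    descriptors (tortuosity, axis-orientation sigma, vessel density, mean
    vessel diameter, bifurcations per vessel length), and group-level
    statistics for phenotype and treatment comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    graphics,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
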