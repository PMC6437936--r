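Package: membranalysis
Title: Structural and Thermotropic Analysis of Model Lipid Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of model lipid membranes displaying
    liquid-ordered/liquid-disordered phase coexistence. Implements global
    analysis of small-angle X-ray scattering (SAXS) curves of vesicle
    suspensions as a mixture of multilamellar (modified Caille structure
    factor) and unilamellar (diffuse) scatterers built on a symmetric
    three-Gaussian electron-density profile, with derived bilayer thickness
    and unilamellar fraction; differential scanning calorimetry (DSC)
    thermogram analysis with baseline subtraction, van't Hoff enthalpy and
    cooperative-unit extraction; and laurdan generalized-polarization (GP)
    imaging of giant unilamellar vesicles with G-factor calibration, ring
    segmentation into coexisting phases and per-phase GP time series.
    Seeded synthetic-data generators for all three modalities provide known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    tiff,
    minpack.lm,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
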