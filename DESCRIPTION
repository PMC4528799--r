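Package: tlsdiffuse
Title: Simulating X-Ray Diffuse Scattering from TLS Structural Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts X-ray diffuse scattering from multi-model structural
    ensembles via the ensemble variance of complex structure factors
    (Guinier's equation), computed by direct summation with tabulated
    atomic form factors. Converts translation-libration-screw (TLS)
    rigid-body parameterizations into explicit coordinate ensembles by
    random sampling or deterministic correlated stepping, validates TLS
    tensors for physical plausibility, and provides reciprocal-space map
    analytics: radial intensity profiles, isotropic-component subtraction
    ("anisotropic maps"), global and resolution-binned Pearson
    correlations, and difference maps. Diffuse intensity between Bragg
    points is sampled by real-space unit-cell expansion with fractional
    Miller indices collapsed back onto the Bragg lattice by voxel
    averaging. Includes generators for synthetic toy structures and
    physically valid random TLS groups, so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
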