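Package: gasmas
Title: Simulation and Inversion of Gas in Scattering Media Absorption
    Spectroscopy Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gas in scattering media absorption spectroscopy
    (GASMAS) of enclosed gas volumes such as neonatal lungs. Simulates
    dual-wavelength tunable diode laser scans (an oxygen A-band line near
    764 nm and a water-vapour line near 820 nm) through turbid tissue
    phantoms, recovers peak absorbances by direct-absorption line fitting,
    inverts them to gas pathlength via the Beer-Lambert law with a
    saturated-water-vapour reference (Arden Buck hygrometry), estimates
    oxygen concentration under the shared-pathlength assumption, and
    applies replicate aggregation, pathlength outlier screening and
    two-sample Kolmogorov-Smirnov comparability tests across
    source-detector configurations.
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
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
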