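Package: cecflux
Title: Processing and Quality Control for Cholesterol Efflux Capacity Plate Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes HDL cholesterol efflux capacity (CEC) from 96-well
    fluorescence plate-reader exports under the two common referencing
    schemes (per-well total fluorescence and time-zero control wells),
    with background and passive-efflux subtraction, triplicate
    coefficient-of-variation quality gating, plate-to-plate correction
    from four on-plate control samples, and resazurin-based cell
    monitoring. Includes the agreement and bias statistics used to
    compare referencing methods (Bland-Altman limits of agreement,
    Michaelis-Menten acceptor saturation fits, cell-seeding bias
    regression) and a synthetic plate generator that emulates the
    assay's error structure for validation and method studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
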