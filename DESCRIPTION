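Package: msotlipid
Title: Label-Free Lipid Quantification and Liver-Function Analysis for
    Multispectral Optoacoustic Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multispectral optoacoustic tomography
    (MSOT) assessment of hepatic steatosis. Provides linear-regression
    spectral unmixing of oxy-/deoxy-haemoglobin, lipid, water and
    indocyanine green with derived total-blood-volume and oxygen-saturation
    metrics; a three-wavelength (700/800/930 nm) difference statistic for
    label-free lipid detection; steatosis grade assignment with full ROC
    machinery (AUROC, DeLong confidence intervals and tests, Youden
    cutoffs); indocyanine-green clearance kinetics for liver-function
    scoring; and a seeded synthetic multispectral data generator (tissue
    forward model with diffusion-theory fluence, phantom dilution series,
    graded cohorts, clearance curves) so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    pracma,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
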