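Package: fluordom
Title: Optical Chemometrics for Dissolved Organic Matter Degradation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing chromophoric and fluorescent dissolved organic
    matter (CDOM/FDOM) in photochemical and microbial degradation experiments.
    Converts absorbance spectra to Napierian absorption coefficients, fits
    exponential spectral slopes (S275:295, S350:400) and SUVA254, corrects
    excitation-emission matrices (blank subtraction, inner-filter effect,
    Raman-unit normalisation, scatter masking), fits non-negative trilinear
    PARAFAC models with split-half validation and Tucker congruence matching,
    computes component maxima, percent contributions and Grubbs-filtered
    percent changes, fits single and double exponential photobleaching decay
    models, and summarises river/plume/ocean incubation campaigns. Includes a
    synthetic campaign generator with known ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tools, minpack.lm, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
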