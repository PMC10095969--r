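Package: growkin
Title: Kinematic Analysis of Cell Division and Expansion in Growing Monocot Leaves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the kinematic analysis of steady-state growing
    monocot leaves. Computes leaf elongation rates from irregularly
    spaced, possibly incomplete time series of leaf length; fits
    cell-length profiles along the leaf axis by local-linear kernel
    regression with a direct plug-in bandwidth selector; and combines
    elongation rates, fitted profiles and measured meristem lengths
    into the classical set of kinematic parameters (cell production
    rate, cell division rate, cell cycle duration, residence times and
    zone sizes). Includes a growth-zone simulator with analytically
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0.0)
Imports: stats, utils, grDevices, graphics, jsonlite
Suggests: testthat (>= 3.0.0), KernSmooth, optparse, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
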