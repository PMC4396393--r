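Package: trxss
Title: Time-Resolved X-Ray Solution Scattering Analysis of Ultrafast
    Protein Structural Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for femtosecond pump-probe X-ray solution scattering
    (TR-XSS) experiments on photoexcitable proteins. Provides a synthetic
    data generator emulating an interleaved-reference pump-probe run,
    reduction of raw frames to averaged difference patterns with
    reduced-chi-square shot screening, difference-Guinier fitting of the
    radius-of-gyration and protein-volume changes at constant electron
    count, damped-oscillation kinetic fitting with Gaussian instrument
    response convolution, and a complex eigenfrequency solver for the
    breathing modes of a homogeneous elastic sphere immersed in a fluid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
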