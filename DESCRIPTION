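Package: osteoadapt
Title: Invertible Model of Cortical Bone Adaptation to Mechanical Loading
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward and inverse modelling of lamellar cortical bone
    adaptation to periodic mechanical loading. Computes the Kelvin-Voigt
    viscoelastic strain response to unit loading waveforms, evaluates an
    explicit mechanostat law for average bone formation rate (BFR/BS),
    propagates an osteocyte-derived calcium-like stimulus through an
    osteocyte-osteoblast process network by steady-state diffusion to
    predict site-specific mineral apposition rate (MAR), and inverts the
    chain to recover the sectional loads (normal force and two bending
    moments) that produce a prescribed MAR distribution. Includes
    Levenberg-Marquardt calibration of the model constants, Watson's U2
    circular goodness-of-fit comparison of MAR maps, seeded synthetic
    fixtures, and a file-based pipeline interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
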