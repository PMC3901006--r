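Package: vsdiglm
Title: Linear-Model Denoising for Voltage-Sensitive Dye Imaging Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-based processing of mesoscopic functional optical imaging
    sessions (voltage-sensitive dye imaging and related modalities). Implements
    the standard blank-subtraction workflow (frames-0 division, blank
    averaging and subtraction, linear detrending) and a per-pixel general
    linear model workflow: a parametric piecewise-cosine response-shape family
    reduced to a signal basis by principal component analysis, physiological
    noise regressors (dye-bleaching exponential, heartbeat Fourier series)
    estimated from blank trials, ordinary least-squares fitting at every
    pixel, fractional-fluorescence (dF/F) extraction, and Durbin-Watson
    residual-whiteness diagnostics. Trials are stored as 4D NIfTI-1 files
    under a session naming convention with a plain-text condition table. A
    seeded synthetic-session generator with ground truth supports validation
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    withr
Config/testthat/edition: 3
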