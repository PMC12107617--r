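Package: qtctbt
Title: Time-Varying QT Interval Correction for Tuberculosis Patients on Treatment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for heart-rate normalisation modelling and QT-interval
    correction in patients treated for active tuberculosis. Implements a
    composite nonlinear mixed-effects heart-rate model (asymptotic
    time-on-treatment recovery, 24 h and 12 h circadian cosine harmonics, an
    Emax effect of the bedaquiline metabolite M2, and power/conditional
    covariate effects) with Laplace marginal-likelihood estimation, stepwise
    covariate selection and visual predictive checks; the QTcTBT time-varying
    correction factor that declines from the pretreatment exponent 0.4081 to
    the Fridericia exponent 0.33 with the heart-rate recovery half-life,
    alongside standard Bazett, Fridericia, Olliaro, Framingham and Van de
    Water corrections; a two-step correction-quality evaluation (per-time-bin
    QTc-versus-HR regression and an SE-weighted slope trend); standard QTc
    prolongation endpoints; and a synthetic-cohort generator emulating the
    design of the phase IIb trials the model derives from.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
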