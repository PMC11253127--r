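Package: nflatrophy
Title: Semi-Mechanistic Modelling of CSF Neurofilament Light Chain and
    Brain Atrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links the neurofilament light chain (NfL) concentration in
    cerebrospinal fluid (CSF) to the rate of whole-brain atrophy through a
    quasi-steady-state mass-balance model. Brain volume follows a quadratic
    age trajectory whose acceleration, in Huntington's disease, scales with
    CAG repeat length through a power law; the NfL released by the shrinking
    brain is cleared by bulk CSF flow at group-specific rates. The package
    provides the structural model and its one-compartment ODE form, a
    synthetic longitudinal cohort generator emulating the HD-CSF study
    design, a joint nonlinear mixed-effects estimator (adaptive
    Gauss-Hermite / Laplace marginal likelihood) for the volume and NfL
    observation streams, model comparison by small-sample corrected BIC,
    prediction bands, residual diagnostics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
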