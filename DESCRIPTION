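Package: asdyn
Title: Multi-Scale Dynamical Models of Autism Spectrum Symptom Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and estimation tools for a mechanistic, multi-timescale
    model of autism-spectrum symptom dynamics grounded in predictive coding,
    information theory and network neuroscience. Implements seven closed-form
    submodels (social-reciprocity resource depletion, multi-channel nonverbal
    effectiveness, sigmoid relationship growth, entropy-modulated stereotypy
    oscillations with an optional non-homogeneous Poisson bout process,
    precision-weighted sameness distress, restricted-interest engagement decay,
    and habituation/sensitisation cumulative sensory load), a normalised
    composite severity index, a hierarchically coupled scenario engine with a
    packaged worked scenario, a synthetic ecological-momentary-assessment data
    generator, and nonlinear least-squares parameter-recovery tooling with
    identifiability diagnostics.
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
    jsonlite,
    yaml,
    minpack.lm,
    lhs,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
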