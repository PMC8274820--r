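Package: multistrain
Title: Multi-Strain Chronic-Infection Epidemic Models with Treatment and Prophylaxis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Compartmental SI models of a chronic multi-strain viral infection with
    within-host strain mutation, non-curative treatment and chemo-prophylaxis.
    Provides constructors and spectral analysis for column-stochastic within-host
    mutation matrices, closed-form and next-generation controlled basic reproduction
    numbers, first-order sensitivity of R0 with respect to the treatment and
    prophylaxis enrollment rates, control-efficiency classification, disease-free and
    endemic equilibria (closed form for the baseline model, numeric for the extended
    model), stiff ODE integration of both models, and scenario sweeps over
    transmissibility, prophylaxis coverage and treatment failure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
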