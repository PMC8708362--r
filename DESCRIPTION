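Package: ferroheat
Title: Specific Loss Power Modelling for Superparamagnetic Hyperthermia
    with Cobalt-Ferrite Nanoparticles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form modelling of heat dissipation by superparamagnetic
    Co(x)Fe(3-x)O4 nanoparticles driven by an alternating magnetic field.
    Implements the Langevin equilibrium magnetization, Debye dynamic
    susceptibility and Neel relaxation to compute the specific loss power
    (SLP/SAR) of a monodisperse spherical ensemble, together with
    composition-dependent material property models (anisotropy constant,
    spontaneous magnetization, density), optimal-diameter search maximizing
    the loss power, and operating-point optimization under the admissible
    biological field-frequency product limit H x f. Provides tidy tabular
    interfaces, ggplot2 figures, a reproducible report generator and a thin
    command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
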