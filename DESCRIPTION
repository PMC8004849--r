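Package: eutectr
Title: Solid-Liquid Equilibria and Physical Properties of Terpene Eutectic Solvents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational characterization of binary terpene eutectic solvent
    systems. Estimates critical properties by the Modified Lydersen-Joback-Reid
    group-contribution method, evaluates empirical correlations for density,
    surface tension and refractive index with percentage relative errors,
    computes ideal and UNIFAC solid-liquid-equilibrium phase diagrams with
    eutectic-point location and deep-eutectic classification, and analyses
    NMR chemical-shift temperature coefficients for hydrogen-bond typing.
    Ships the melting data, compositions and correlation constants of the
    four menthol/thymol/borneol/camphor systems as built-in fixtures, plus
    synthetic-data generators and brute-force oracles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
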