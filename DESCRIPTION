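Package: crowdna
Title: Coarse-Grained DNA Thermodynamics and Kinetics in Crowded Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale coarse-grained model of DNA duplexes, hairpins and
    strand-displacement systems immersed in inert spherical crowders. Provides
    a nucleotide-level representation with native-only base pairing and
    excluded-volume crowder interactions, umbrella-sampled Monte Carlo
    thermodynamics (free-energy profiles, melting temperatures with bulk
    extrapolation, van't Hoff analysis), Brownian-dynamics kinetics with
    forward flux sampling for hybridization, hairpin closing and toehold
    mediated strand displacement, and scaled-particle-theory predictions of
    crowding-induced stabilization with effective-radius fitting. All test
    systems are generated programmatically; results are returned as tibbles
    with broom-style tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
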