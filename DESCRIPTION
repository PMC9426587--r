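Package: trichodiel
Title: Diel Physiology Model of a Trichodesmium Trichome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained diel simulation of carbon fixation, N2 fixation,
    respiratory protection and intracellular oxygen in a single Trichodesmium
    trichome. Photosynthetic electron transport is split dynamically between
    linear and alternative (Mehler-type) pathways so that ATP and NADPH supply
    track instantaneous demand; N2 fixation has priority for both currencies
    and is inhibited by intracellular O2. Includes a spatially segregated
    (diazocyte) model variant with intercellular transfer losses, cross-
    membrane O2 diffusion for cylindrical trichomes, an end-of-day biosynthesis
    solve yielding a daily growth rate, a multistart growth-maximizing
    parameter optimizer, and scripted sensitivity and ablation experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    lhs,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
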