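Package: socetools
Title: Stochastic Modelling and Quantitative Analysis of Store-Operated
    Calcium Entry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying redox modulation of store-operated calcium
    entry through STIM1-gated Orai1 channels. Provides a stochastic
    reaction-diffusion simulator of Orai1 dimer diffusion, STIM1 trapping
    and tetramer/hexamer channel assembly on a membrane lattice, including
    oxidation-locked non-conducting channels and the resulting CRAC current;
    three-cube sensitized-emission FRET analysis with bleed-through
    calibration and cluster filtering; FRAP recovery-curve normalization and
    exponential time-constant fitting; patch-clamp current-density, I-V and
    tail-current apparent-open-probability analysis; and synthetic-data
    generators with known ground truth for every input the analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    EBImage
Config/testthat/edition: 3
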