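Package: perktriad
Title: Feedback-Loop Analysis of the ATF4-GADD34-CHOP Triangle in the
    PERK Branch of the Unfolded Protein Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ordinary differential equation model of the PERK branch of the
    endoplasmic reticulum unfolded protein response, centred on the
    ATF4-GADD34-CHOP regulatory triangle.  Simulates tolerable and excessive
    ER stress, guanabenz treatment, siRNA knockdown and overexpression as
    time-structured scenarios; calibrates rate constants against a set of
    qualitative constraints encoded from time-course experiments; scores
    model variants against an encoded phenotype call matrix to discriminate
    network wirings with and without the GADD34-to-ATF4 positive and
    CHOP-to-ATF4 negative feedback loops; and generates synthetic
    qPCR/densitometry-like replicate measurements for robustness analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
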