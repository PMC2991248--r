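Package: lariatr
Title: Branch Point Prediction in Mammalian Introns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the splicing branch point (BP) of mammalian introns from
    sequence alone. Candidate BP 9-mers are enumerated inside the AG exclusion
    zone (AGEZ) of each intron, scored with a position-dependent first-order
    Markov model of the branch-site signal, and combined with downstream
    polypyrimidine-tract (PPT) features in a support vector machine that ranks
    candidates per intron. Also provides the conserved-pentamer pipeline that
    builds a high-confidence positive training set from multi-species
    alignments of intron 3' ends, Hamming-distance and PWM baseline methods
    with benchmark evaluation, and a synthetic intron generator with planted
    branch points for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
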