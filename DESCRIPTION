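Package: seqpka
Title: Sequence-Based Protein pKa Prediction with Ensemble Shift Regressors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts pKa values of titratable protein residues (Asp, Glu,
    His, Cys, Tyr, Lys) from sequence alone. Per-residue embedding vectors
    from a protein language model backend feed separately trained acidic and
    basic ensembles of multilayer perceptrons that regress pKa shifts
    relative to model-peptide solution values; ensembles are pretrained on a
    large teacher-labelled corpus and fine-tuned on experimental data.
    Provides Henderson-Hasselbalch protonation-state classification,
    ensemble standard errors, a repeated hold-out evaluation harness with
    pretraining/channel-separation ablations and transformer layer sweeps,
    and a fully synthetic planted-signal data generator so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
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
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
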