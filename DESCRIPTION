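Package: admetscreen
Title: DMPK Compliance Profiling of Compound Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for in silico drug-metabolism and pharmacokinetics (DMPK)
    triage of compound libraries. Computes formula-defined physico-chemical
    descriptors from 3D structures (solvent-accessible surface area and its
    hydrophobic portion, molecular volume, globularity, cohesion index,
    hydrogen-bond counts, rotatable bonds), scores compounds against the
    property ranges spanned by 95% of known drugs to give a violation count
    (number of "stars"), classifies drug-like, lead-like and fragment-like
    subsets, evaluates Rule-of-Three oral bioavailability, applies
    similarity-adjusted property prediction and transdermal-rate models, and
    summarises libraries as compliance tables and binned distributions. A
    synthetic-library generator with planted compliance fractions supports
    fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    igraph,
    optparse,
    stats,
    utils,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
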