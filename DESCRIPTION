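Package: htpbk
Title: High-Throughput Whole-Body Physiologically Based Kinetic Modelling
Version: 0.1.0
Authors@R:
    person("HT-PBK", "Maintainers", email = "maintainers@htpbk.dev", role = c("aut", "cre"))
Description: A generic whole-body physiologically based kinetic (PBK) simulator
    together with the machinery needed to benchmark high-throughput PBK
    parameterisation strategies against observed human pharmacokinetic data.
    Compound properties (lipophilicity, pKa, fraction unbound, solubility,
    clearance, intestinal permeability) are held as source-tagged records and
    resolved through pluggable parameterisation strategies; tissue:plasma
    partition coefficients are computed with five published method families;
    hepatocyte intrinsic clearance is scaled to whole-liver clearance; oral
    dosing supports formulation-specific dissolution, a solubility cap and
    permeability-limited absorption.  Concentration-time predictions are scored
    with profile-level relative and absolute Log2 errors, non-compartmental
    summary metrics and fold-range statistics, aggregated by per-compound and
    per-strategy medians, and strategy grids plus a three-step evaluation
    workflow rank parameter sources.  A synthetic-data generator emulates
    multi-study IV/PO datasets with configurable tool biases and noise so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
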