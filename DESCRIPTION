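Package: circdose
Title: Circulating-Blood Dose Simulation for Radiotherapy Treatment Plans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the radiation dose absorbed by circulating blood during
    fractionated radiotherapy. Blood is discretized into computational
    particles that move through a flow-weighted compartment model of the
    whole-body circulation (ICRP 89 reference physiology); during simulated
    beam-on windows, particles residing in irradiated organs accumulate dose
    sampled from organ-level dose-volume histograms (DVHs), yielding a
    circulating-blood DVH and the usual scalar metrics (Dmean, Dn%, VxGy).
    Also provides DVH input/output and plan-quality indices (homogeneity and
    conformity), a seeded synthetic head-and-neck plan-cohort generator
    covering photon/proton modalities and blood vessel-sparing constraint
    levels, paired nonparametric comparisons (Friedman, Wilcoxon signed-rank,
    Bonferroni), and an end-to-end study pipeline with a reproducibility
    manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
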