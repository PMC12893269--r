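Package: ictalmea
Title: Ictal-Like Event Analysis for Microelectrode Array Recordings and
    Chloride Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of induced ictal-like network activity in multichannel
    microelectrode array (MEA) recordings from acute brain slices: PCA/ICA
    source separation, maxed-interval detection of ictal-like events (ILEs)
    and interictal-like discharges (IILDs), per-source outcome metrics, and
    Bayesian random-intercept mixed models for paired before/after designs.
    Also provides single-neuron chloride electrophysiology calculators
    (Goldman-Hodgkin-Katz and Henderson-Hasselbalch equations, I-V reversal
    estimation, liquid junction potentials, capacitive-transient passive
    properties, all-point-histogram tonic current estimation) and a seeded
    synthetic-data generator with known ground truth for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
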