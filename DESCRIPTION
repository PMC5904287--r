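Package: neurostate
Title: Dynamic Neural State Identification in Deep-Brain Local Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies dynamic synchronization states of theta (6-9 Hz) and
    alpha (9-12 Hz) oscillations in deep-brain local field potentials.
    Oscillations are sparsely represented by a running-window wavelet packet
    transform at 384 Hz, synchronization is discriminated against an adaptive
    minimax threshold estimated from a trailing a-priori window of
    coefficients with an n1/n2 consecutive-window confirmation rule, and the
    joint alpha-theta neural state is binary encoded.  Includes the
    preprocessing chain for raw recordings, a trapezoid-modulated simulation
    benchmark with ground-truth labels, sensitivity/specificity and delay
    scoring, parameter sweeps, a global fixed-threshold baseline, and
    Spearman correlation of state occurrence with clinical outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    signal,
    MASS,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
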