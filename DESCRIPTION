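Package: mtupower
Title: EMG-Driven Estimation of Muscle-Tendon Unit Power During Walking Push-Off
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An EMG-driven ankle musculoskeletal model for walking. Maps
    normalized muscle excitation envelopes to plantarflexor muscle-tendon unit
    (MTU) forces through muscle size and pennation, calibrates a per-trial
    electromechanical delay by cross-correlation against inverse-dynamics ankle
    power and a force scaling constant by Push-off peak matching, and
    decomposes ankle joint power into per-MTU contributions. Accounts for the
    multiarticular flexor digitorum/hallucis longus (FDHL) muscles that cross
    the ankle, the longitudinal arch, and the metatarsophalangeal joints, and
    quantifies how much inverse-dynamics ankle Push-off power overestimates net
    plantarflexor MTU power. Includes a forward-consistent synthetic treadmill
    gait generator with known ground truth, the standard EMG and kinematics
    conditioning chain (zero-lag Butterworth filtering, stride segmentation and
    averaging), and a Monte Carlo sensitivity analysis over maximum-activation
    uncertainty.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
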