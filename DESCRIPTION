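Package: tactstim
Title: Biomimetic Tactile Neurostimulation Design and Electrophysiology Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing biomimetic peripheral-nerve stimulation patterns
    from simulated foot-sole tactile afferent populations and for analysing how
    stimulation-evoked neural activity compares with natural touch. Includes a
    parametric simulator of SA/FA mechanoreceptor firing under ramp-and-hold
    pressure stimuli, frequency-modulated and conventional pulse-train encoders
    with charge-safety validation, a ground-truthed generator of multichannel
    extracellular recordings, an electrophysiology pipeline (robust noise
    estimation, comb/Butterworth filtering, artifact blanking, threshold spike
    detection, PSTH, LFP trigger averaging, Kullback-Leibler comparison of LFP
    amplitude distributions, current source density with shuffled-channel null
    correlations), and nonparametric summaries for sensation-rating and
    functional-task tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
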