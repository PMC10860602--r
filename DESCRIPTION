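Package: whiskephys
Title: Whisking Kinematics and Neural Activity Analysis for Awake Rodent Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify whisking-related neural activity in awake rodent
    recordings. Decomposes whisker angle traces into phase, amplitude, midpoint
    and setpoint via band-pass filtering and the Hilbert transform, segments
    recordings into quiet and whisking epochs, classifies sorted units by
    waveform shape and whisking modulation, builds equal-probability tuning
    curves with a two-step ANOVA plus shuffle significance test, quantifies
    subthreshold membrane-potential dynamics including slow-wave band power and
    whisking phase-locked modulation with a circular-shift null, localizes
    cortical layer 4 from touch-evoked laminar field potentials by current
    source density, and compares light-on versus light-off conditions. A
    synthetic-data generator with fully known ground truth supports validation
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    mgcv,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
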