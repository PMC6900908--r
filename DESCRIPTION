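Package: thetabeat
Title: Binaural-Beat/ASMR Sleep-Induction Stimuli and EEG Entrainment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing combined binaural-beat and ambient natural-sound
    (ASMR-style) auditory stimuli for sleep induction and for analysing their
    electroencephalographic (EEG) entrainment effects. Synthesizes a 6 Hz binaural
    beat (250/256 Hz dichotic tones) mixed with surrogate natural sound at fixed
    decibel ratios and writes standard WAV files; simulates multi-channel EEG
    cohorts with 1/f background activity and a stimulus-locked theta response;
    reproduces a standard preprocessing chain (downsampling, zero-phase FIR
    band-pass, 60 Hz notch); computes Welch band powers over a seven-region
    10-10 montage, the midline 6 Hz peak, and the frontal alpha laterality index;
    scores the 32-item Brunel Mood Scale; and runs the paired-t / ANOVA / effect
    size battery used to compare stimulation conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
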