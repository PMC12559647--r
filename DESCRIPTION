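Package: caeqsim
Title: Simulated Distortion-Detection and Audio-Quality Experiments in
    Complex Acoustic Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation of psychoacoustic experiments on the
    audibility and perceived quality of audio distortions in complex
    acoustic environments. Provides calibrated signal generators (pink
    noise, speech-like surrogates, maskers), four parametric distortion
    families (spectral ripple, cubic soft-clipping saturation with THD
    metrology, intensity offsets, spatial offsets) and a MUSHRA-style
    anchor recipe, shoebox binaural room impulse response synthesis
    (image-source early part, feedback-delay-network tail, spherical-head
    binaural cues) with T60 and direct-to-reverberant metrology, NAL-R
    audiogram-based linear compensation with pure-tone averages,
    a transformed up-down (1-up/2-down) 3-AFC adaptive staircase engine,
    simulated psychometric listeners and rating cohorts, and the signal
    distortion-to-detection ratio (SDDR) analysis linking detection
    thresholds to suprathreshold quality ratings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
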