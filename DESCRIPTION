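Package: amygcontext
Title: Context-Dependent Baseline Modulation in Amygdala Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for context-dependent baseline modulation of
    spiking activity recorded during alternating blocks of passive airflow
    stimulation and social grooming. Provides a session data model with
    plain-text readers and writers, a seeded synthetic-session generator
    (inhomogeneous Poisson spike trains, integrate-to-threshold EKG with
    respiratory sinus arrhythmia), stimulus-responsivity testing, effect-size
    based context classification of baseline firing, single-neuron and
    pseudo-population linear SVM decoding with permutation and bootstrap
    nulls, and heart-rate / RSA autonomic characterization including
    high-heart-rate episode detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
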