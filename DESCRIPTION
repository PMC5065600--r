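Package: nextprep
Title: Real-Time Prediction of Remaining Surgical Procedure Duration from
    Electrosurgical Activation Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts, in real time, the remaining duration of a laparoscopic
    cholecystectomy from the activation pattern of the electrosurgical device,
    and advises the operating-room team when to start preparing the next
    patient. Includes a seeded, phase-structured simulator of electrosurgical
    current traces (the training and test cohorts), burst detection on raw
    current traces, prefix feature extraction, a bank of per-decision-time
    support vector machine classifiers, the sequential advice protocol
    (first decision at 15 min, re-predictions every 5 min, 45-min cap, 25-min
    preparation lead time), and a timing-error evaluation harness with
    too-early/acceptable/too-late banding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
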