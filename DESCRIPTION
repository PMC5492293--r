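Package: turngait
Title: Faller Classification from Turn and Straight-Walking Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for prospective-faller classification in older adults
    from tri-axial accelerometers worn on the pelvis and both shanks during a
    six-minute walk test. Provides a seeded synthetic session generator,
    resampling and synchronization, step detection, walking-turn segmentation
    with five-step standardized turns, a 74-feature gait feature bank per
    section (directional acceleration statistics, first-quartile FFT fraction,
    even/odd harmonic ratio, cadence, stride time) aggregated to 296 features
    per participant and condition, three feature selectors, six classifiers,
    and a ranked cross-validation protocol comparing turn against straight
    walking features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
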