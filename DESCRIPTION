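Package: varusthrust
Title: Quantifying Varus Thrust from Wearable IMU Gait Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative assessment of varus thrust during walking from
    tibia- and femur-mounted inertial measurement units (IMUs). Detects heel
    contact and toe-off from tibial acceleration, extracts the first half of
    each stance phase and the swing phase, and computes the speed-adjusted
    root-mean-square thrust index A-RMS (mediolateral stance acceleration RMS
    divided by mean three-plane swing angular-velocity RMS). Includes the
    reliability and discrimination statistics used to validate such an index
    (ICC(1,1), Cohen's d, unpaired t-tests from raw or summary data, Pearson
    correlation, empirical ROC with Youden cutoff, binormal AUC), a synthetic
    treadmill-gait generator with ground-truth events for end-to-end testing,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
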