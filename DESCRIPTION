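Package: kmdiff
Title: Quantile Survival Time Difference Curves with Bootstrap Bands
Version: 1.0.0
Author: kmdiff developers
Maintainer: kmdiff developers <kmdiff@example.org>
Description: Estimates the quantile survival time difference curve, the
    horizontal gap between two Kaplan-Meier curves expressed as a function
    of the survival probability p.  Setting p = 0.5 gives the familiar
    median survival time difference; varying p over (0, 1] gives the whole
    curve.  Sampling variability is visualized either by a bundle of
    resampled bootstrap step functions (Efron's censored-data bootstrap)
    or by a pointwise percentile confidence band, with a conservative
    weighted extension of the band below the probability at which every
    bootstrap replicate is defined.  Includes a synthetic-data generator
    for right-censored two-group samples with known population quantile
    differences, tidy delimited input/output, plotting in the customary
    orientation (survival probability on the vertical axis), and a
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
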