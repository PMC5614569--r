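Package: dsaflow
Title: Automatic Flow Analysis of Dynamic Digital Subtraction Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fully automatic hemodynamic analysis of dynamic digital
    subtraction angiography (DSA) series. Frames are motion-corrected by
    keypoint registration to the pre-contrast reference, decomposed into
    arterial, capillary and venous phases by temporal independent component
    analysis (FastICA), segmented by Otsu thresholding into vessel masks, and
    summarized as time-density curves fitted with the gamma-variate bolus
    model. The angiographic mean transit time (aMTT) is the full width at
    half maximum of the capillary-phase curve; the cerebral circulation time
    (CCT) is the time-to-peak difference between a parietal-vein and a
    cavernous carotid ROI. A synthetic biplane phantom generator with known
    compartment kinetics provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
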