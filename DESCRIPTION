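Package: petacdose
Title: CT Exposure and Reconstruction Effects on PET Attenuation Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for assessing how CT acquisition
    exposure (tube current, voltage, pitch) and CT reconstruction algorithm
    (filtered back projection versus iterative reconstruction) affect PET
    quantitation through the CT-derived attenuation-correction map. Provides a
    digital anthropomorphic torso phantom, a slice-stacked CT/PET simulator
    with an ordered-subset expectation-maximisation (OSEM) reconstruction,
    region-of-interest SUV statistics (mean, maximum, SD, coefficient of
    variation), paired comparisons of matched reconstructions, and a
    voxel-wise analysis of test reconstructions against a reference
    reconstruction using a quantitatively-significant-difference threshold.
    Also analyses user-supplied co-registered NIfTI volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
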