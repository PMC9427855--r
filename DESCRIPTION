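Package: taucl
Title: Interpretable 3D CNN Mapping of Tau-PET Topography to Amyloid Centiloid
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to learn and interpret a nonlinear mapping from 3D tau-PET
    volumes to a scalar amyloid-beta Centiloid value. Provides a synthetic
    phantom generator with a planted, Centiloid-dependent regional signal
    structure; image preprocessing (min-max scaling, cerebellar-reference SUVR,
    masking, Gaussian FWHM smoothing); a compact 3D convolutional network
    regressor trained by RMSprop with k-fold cross-validation; exact gradient
    saliency maps; voxel-wise general linear models with permutation-based
    family-wise error control and cluster-extent thresholding; and cluster
    occlusion analyses including out-of-sample R-squared changes and
    LOESS-smoothed strength-of-association curves across the Centiloid
    continuum.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
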