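Package: rhizospec
Title: Hyperspectral Image Processing for Root Phenotyping in Rhizoboxes
Version: 1.0.0
Authors@R: person("Rhizospec", "Developers", email = "rhizospec@example.org",
    role = c("aut", "cre"))
Description: Processing pipeline for near-infrared hyperspectral line-scan
    (push-broom) images of soil-filled rhizoboxes: reflectance normalization
    against white and dark standards, dead-pixel masking, a factorial bank of
    chemometric spectral pre-treatments (log-linearization, polynomial
    de-trending, Savitzky-Golay derivatives, asymmetric least squares baseline
    correction, standard normal variate), information-criterion and
    Bhattacharyya-distance based pre-treatment and waveband selection,
    unsupervised and supervised root-soil segmentation (multilevel Otsu
    thresholding, k-means, fuzzy c-means, linear support vector machine),
    Fourier-domain phase-correlation stitching of scan strides, skeleton-based
    root length estimation, radial (centre-to-border) tissue classification
    with error-correcting output codes over decision trees, and exponential
    root-decay modelling from water and structural-carbohydrate absorption
    features. Includes a seeded synthetic rhizobox scene generator with full
    ground truth so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
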