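Package: sperf
Title: Self-Supervised Coordinate Networks for Sparse-View SPECT
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Per-scan self-supervised synthesis of skipped SPECT projection
    views with a coordinate-based multilayer perceptron, embedded in a
    complete sparse-view SPECT pipeline: a digital hot-sphere phantom
    acquisition simulator with Poisson counting noise, attenuation,
    depth-dependent collimator response and scatter windows; angular
    linear-interpolation and Bernoulli-thinning baselines; OS-EM
    reconstruction with attenuation, PSF and triple-energy-window scatter
    correction; and quantitative image-quality metrics (NRMSD, activity
    recovery, background noise, CNR and relative measures).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
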