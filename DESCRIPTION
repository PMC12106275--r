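Package: cryowave
Title: Noise-Robust Subtomogram Classification with Wavelet Encoders and
    Out-of-Distribution Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies 32x32x32 cryo-electron tomography subtomograms with a
    3D discrete-wavelet-transform (DWT) downsampled residual encoder, an
    adaptive cosine / t-vMF similarity classifier, and a Mahalanobis-distance
    out-of-distribution detector that discards particles from unknown classes
    instead of mislabelling them. Includes the Haar and Cohen-Daubechies-
    Feauveau biorthogonal filter banks in matrix and convolution form, a
    synthetic volumetric phantom simulator with configurable signal-to-noise
    ratio, MRC volume input/output, training and inference orchestration, and
    an FPR95/AUROC/accuracy evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
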