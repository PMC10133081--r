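Package: regganct
Title: Registration-Guided Adversarial CBCT-to-Synthetic-CT Translation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for improving the Hounsfield-unit fidelity of thoracic
    cone-beam CT (CBCT) by translating it to a synthetic CT (sCT) with a
    generative adversarial network trained jointly with a registration
    network (RegGAN), so that spatially misaligned CBCT/CT pairs can be
    used as training data without prior deformable registration. Includes
    a seeded thoracic phantom simulator (planning CT, deformed
    treatment-day anatomy, artifact-degraded CBCT, ROI masks, toy dose),
    preprocessing (rigid and multiresolution B-spline registration, HU
    clipping and normalization), 2.5D slice-wise inference, image-quality
    evaluation (masked MAE/RMSE/PSNR, per-ROI HU statistics, histograms,
    paired Wilcoxon tests), and dose comparison (global gamma index,
    DVH curves and scalar DVH parameters).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
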