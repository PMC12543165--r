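Package: vesselleak
Title: Single-Vessel Blood-Brain Barrier Leakage Analysis on Synthetic
    Vascular Phantoms
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying blood-brain-barrier (BBB) leakage at the
    single-vessel level from 4D two-photon time-lapse stacks. Implements
    seeded synthetic vascular phantoms with two-compartment extravasation
    kinetics and full ground truth; image conditioning (FWHM-parameterized
    Gaussian smoothing, rolling-ball background subtraction, flat-field
    normalization, affine 3D registration); vessel skeletonization, branch
    ordering and arteriole/capillary/venule classification; 5-15 micron
    perivascular shells with nearest-vessel ownership; conventional leakage
    indices (AUC, dF/F0, dF/dt); a UMAP-distance leakage index with k-means
    cluster composition and ROC diagnostics; Patlak Ktrans and Renkin-Crone
    flow-normalized permeability; and Radon-transform line-scan red-blood-cell
    velocimetry. All stages are exercised end-to-end on synthetic phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    uwot,
    digest,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    FNN
Config/testthat/edition: 3
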