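Package: mammoenhance
Title: Mammogram Contrast Enhancement, Pectoral Muscle Removal and
    Enhancement Quality Metrics
Version: 1.0.0
Authors@R:
    person("Mammoenhance", "Developers", email = "mammoenhance@example.org",
           role = c("aut", "cre"))
Description: A five-stage contrast-enhancement pipeline for digital mammograms:
    per-channel morphological background uniformity (top-hat/bottom-hat),
    PCA-based fusion of the three color channels into a well-contrasted
    grayscale image, automatic seed-based region growing to remove the
    pectoral muscle on mediolateral-oblique views, and Laplacian-of-Gaussian
    normalization followed by coherence-enhancing anisotropic diffusion with
    an entropy-based stopping rule.  Includes K-means intensity clustering to
    expose abnormal regions, the PSNR / log-contrast / EME enhancement-quality
    metrics, histogram-equalization baselines (HE, CLAHE, BBHE), and a
    synthetic CC/MLO mammogram phantom generator with ground-truth masks so
    the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    png,
    jpeg,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
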