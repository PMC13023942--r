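Package: fenoct
Title: Frequency-Aware Self-Supervised Denoising for MEMS-OCT B-Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Self-supervised speckle and artifact reduction for optical
    coherence tomography (OCT) cross-sections acquired with MEMS-scanned
    probes. Provides a layered-tissue speckle phantom simulator with the
    three characteristic MEMS-OCT degradations (multiplicative speckle,
    periodic low-frequency background, coherent stripe artifacts),
    classical preprocessing (stack-based stripe removal and Fourier notch
    filtering), deterministic Neighbor2Neighbor subsampling into
    complementary half-resolution pairs, a frequency-enhanced UNet built
    on Haar-wavelet spectral pooling and dilated receptive-field blocks
    with its own reverse-mode training engine, a three-term
    frequency-aware loss with the Neighbor2Neighbor regularizer, and
    SNR/PSNR/SSIM evaluation against pseudo-clean or true-clean
    references.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
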