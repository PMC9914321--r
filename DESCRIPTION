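Package: mammofuse
Title: Optimized S-Curve Contrast Enhancement and Wavelet Fusion for Breast Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contrast elevation toolkit for mammographic and tomosynthesis
    images. Applies a sigmoid (S-curve) gray-level transform, globally or per
    tile, with the asymptote parameters tuned by particle swarm optimization
    against the block-contrast enhancement measure (EME). The original and
    enhanced images are then fused in the wavelet domain under the maximum
    coefficient-selection rule to retain diagnostic features. Includes a full
    quality-metric suite (entropy, EME, AMBE, standard deviation, universal
    image quality index), a reproducible mammogram-like phantom generator,
    readers and writers for PGM/PNG/TIFF/JPEG, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jpeg,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
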