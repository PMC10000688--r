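Package: stainnorm
Title: Stain Normalization of H&E Whole-Slide Images with Reader-Study
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated stain normalization of hematoxylin-and-eosin
    (H&E) histology images against a pathologist-chosen target image:
    tissue detection, white-balance illuminant correction, optical-density
    stain separation (Macenko singular-direction estimation), and
    per-stain chromatic-profile matching.  Reads and writes tiled
    pyramidal TIFF whole-slide images (200x-equivalent output, JPEG
    quality 80) with resolution metadata.  Ships a Beer-Lambert phantom
    generator with known ground truth (including reddish, greyish and
    weak-staining degradations), a paired two-pathologist reader-study
    simulator, and the matching evaluation statistics: quadratic weighted
    Cohen's kappa, paired t-tests, robust distribution summaries and
    Grade-Group confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jpeg,
    png,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
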