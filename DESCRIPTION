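Package: warnscan
Title: Detection and Compliance Auditing of Tobacco Health-Warning Labels in Promotional Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-layer computer-vision pipeline for detecting boxed,
    black-bordered health-warning labels in still images of social-media
    tobacco promotions. Candidate regions are found by dark-pixel
    thresholding and morphological cleanup, filtered by contour area,
    tested for quadrilateral shape, and confirmed by optical character
    recognition of the "warning" keyword. Detections are scored against
    the FDA advertising rules (at least 20 percent of the advertisement
    area, upper-portion placement) and summarised over an image corpus.
    Includes a seeded synthetic-fixture generator with ground-truth
    manifests, negative binomial mixed-effects modelling of post
    engagement (likes and comments) with incidence-rate-ratio reporting,
    variance-inflation diagnostics, and Cohen's kappa for intercoder
    reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    glmmTMB,
    jpeg,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    car,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
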