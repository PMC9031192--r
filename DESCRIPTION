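Package: otospectra
Title: Color-Channel Dependence Analysis for CNN-Based Otoscopy Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for studying how the color channel of otoscopy imagery
    affects convolutional-network diagnosis of middle and external ear
    conditions (normal, chronic otitis media, otitis media with effusion,
    earwax plug). Provides a seeded synthetic otoscopy-video generator with
    channel-localized class signal, frame-domain filtering by histogram
    Kullback-Leibler divergence, blur rejection by variance of the Laplacian,
    PCA plus k-means keyframe summarization, seven spectral input renderings,
    a from-scratch VGG-style convolutional network with a desk-scale tiny
    variant, one-vs-all macro-averaged evaluation metrics with ROC curves,
    and Grad-CAM class activation maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    png,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
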