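Package: nucseg
Title: Automated Cell Nuclei Segmentation for Cytology Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage framework for segmenting cell nuclei in cytology
    microscopy images such as Pap-stained pleural effusion slides. Provides
    preprocessing (resizing, grayscale conversion, five denoising filters,
    three contrast enhancers, PSNR and contrast-improvement-index quality
    metrics), twelve interchangeable segmentation methods (six global
    histogram thresholding criteria, local adaptive thresholding, k-means,
    fuzzy c-means and mean-shift clustering, Chan-Vese level sets, and a
    convex-relaxed continuous min-cut), morphological postprocessing
    (small-object removal, disk opening and closing), pixel- and
    nucleus-level evaluation against ground truth (precision, recall,
    F-measure, Jaccard, Dice, nuclei detection rate), and a seeded
    synthetic cytology-scene generator so the whole pipeline can be
    exercised and benchmarked without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    tiff,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
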