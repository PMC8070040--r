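Package: heartseg
Title: Unsupervised Whole-Heart Segmentation of Chest CT by K-Means
    Thresholding and a Morphological Convex-Hull Cascade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments the whole heart (four chambers, coronary region and
    descending aorta) from non-contrast chest CT volumes without any training
    data. Intensity thresholds are derived from 1-D K-Means centroids (mean of
    centroids for the body foreground, maximum centroid for the spine) and a
    hierarchical cascade of binary-morphology masks peels away air, lungs and
    spine via convex hulls, with a cross-slice lung-hull refinement for slices
    where the lungs recede. Includes exact histogram-based silhouette scoring
    of the clusterings, image-level IoU/overall-accuracy evaluation, a labeled
    synthetic chest-CT phantom generator for end-to-end testing, and readers
    and writers for DICOM series, NIfTI and PNG masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    png,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
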