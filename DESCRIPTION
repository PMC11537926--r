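Package: fuzzyct
Title: Fuzzy C-Means Segmentation of Intracranial Hemorrhage in Brain CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of intracranial hemorrhage in non-contrast brain CT by
    fuzzy C-means clustering. Implements the standard fuzzy C-means baseline and
    an improved variant combining intuitionistic fuzzification of the gray scale,
    a Gaussian kernel-induced distance, a spatial neighborhood constraint and a
    hesitation-degree membership correction. Includes CT input/output (DICOM
    series, NIfTI, PNG) with Hounsfield-unit windowing, intracranial structure
    extraction, an edge detector based on the Laplacian of Gaussian with boundary
    intensity filtering, region-growing lesion extraction with hemorrhage volume
    quantification, cluster validity indices and segmentation metrics,
    label-synchronized data augmentation, and a synthetic brain phantom generator
    for fully reproducible evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    png,
    igraph,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
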