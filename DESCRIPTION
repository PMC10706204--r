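Package: cfstopo
Title: Automated Grading of Corneal Fluorescein Staining with Multiscale
    Topological Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automatic grading of corneal fluorescein staining (CFS)
    in anterior-segment slit-lamp photographs on the 0-4 Ocular Staining
    Score (OSS) scale. The pipeline locates the inferior corneal region of
    interest via Otsu sclera segmentation and Daugman's integrodifferential
    operator, segments staining dots and patches by morphological top-hat
    by reconstruction, extracts a 974-feature signature (837 radiomic
    texture features over nine image forms, 9 morphological features, and
    128 multiscale dilation-graph topological features), selects a compact
    signature through an ANOVA / Pearson-redundancy / backward-elimination
    / tree-importance cascade, and grades images with classical
    classifiers. A synthetic anterior-segment image generator with ground
    truth makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    e1071,
    rpart,
    randomForest,
    xgboost,
    caret,
    png,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
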