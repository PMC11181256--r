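Package: eustex
Title: Texture-Feature Classification of Gastric Mesenchymal Tumors on Endoscopic Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-assisted analysis of endoscopic ultrasonography (EUS) still
    images for differentiating gastrointestinal stromal tumors (GISTs) from benign
    gastric mesenchymal tumors (leiomyoma, schwannoma). Extracts second-order
    texture features from polygon-annotated lesion regions: 48 gray-level
    co-occurrence matrix (GLCM) descriptors over 3 distances and 4 directions,
    3 global gray statistics, and 15 gray-gradient co-occurrence matrix (GGCM)
    descriptors built on Sobel gradient magnitudes quantized to 32 levels.
    Classifies lesions with a leave-one-out cross-validated linear support vector
    machine and evaluates discrimination with confusion metrics, DeLong ROC/AUC
    inference, paired AUC tests, and chi-square comparison against endoscopist
    reader performance. Includes a seeded generator of synthetic speckled
    EUS-like lesion cohorts with a controllable between-class texture difference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    EBImage,
    graphics,
    jsonlite,
    pROC,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
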