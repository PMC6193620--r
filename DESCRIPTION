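Package: neolus
Title: Computer-Assisted Gray-Scale and Texture Analysis of Neonatal Lung Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies neonatal respiratory status from B-mode lung
    ultrasound still frames. Builds constant-area regions of interest
    anchored to a traced pleural line, computes first-order gray-scale
    statistics and a 44-dimensional gray-level co-occurrence matrix (GLCM)
    texture feature vector (22 features along horizontal and vertical
    2-pixel offsets), and relates both to oxygenation indices
    (PaO2/FiO2 ratio, alveolar-arterial gradient) through support vector
    regression with leave-one-patient-out cross-validation, principal
    component feature reduction, and the usual evaluation statistics
    (Spearman correlation with confidence intervals, Cohen's kappa,
    ROC/AUC). Ships a synthetic cohort generator that emulates the four
    standard severity grades of subpleural texture so the full pipeline is
    testable without clinical images.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
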