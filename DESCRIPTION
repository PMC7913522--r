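Package: mriqa
Title: No-Reference Quality Assessment of Magnetic Resonance Images by
    Fused Convolutional Networks and Support Vector Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for no-reference image quality assessment (NR-IQA) of
    magnetic resonance (MR) scans. Several convolutional backbones are
    truncated at their global-average-pooling layer, fused by feature
    concatenation, and jointly fine-tuned for quality regression; an
    epsilon-support-vector regression with a radial basis kernel is then
    trained on the concatenated pooled features to predict mean opinion
    scores. The package also provides the standard IQA evaluation
    protocol (SRCC, KRCC, PLCC after a five-parameter logistic mapping,
    RMSE, grouped train/test splits, cross-database testing, and Wilcoxon
    rank-sum significance scoring), readers and writers for 16-bit MR
    images (PNG, TIFF, DICOM) with subjective-score tables, and a
    seedable synthetic MR-phantom benchmark with severity-graded
    undersampling ghosting, Rician noise, and blur.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
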