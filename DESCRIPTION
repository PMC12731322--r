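Package: raxseg
Title: Hybrid Attention U-Net Segmentation of Hand Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weakly supervised segmentation of 2-D hand radiographs with a
    dual-attention (CBAM and scSE) encoder-decoder network. Provides a seeded
    synthetic hand-radiograph phantom generator, intensity and geometric
    preprocessing with mask-consistent augmentation, CLAHE plus Otsu
    pseudo-mask generation for weak supervision, a pluggable feature-pyramid
    encoder with three attention-gated up-sampling blocks, composite training
    objectives including the Lovasz hinge, overlap, boundary and
    surface-distance evaluation metrics with bootstrap summaries, a
    patient-level training and ablation harness, and architecture profiling
    (parameter and multiply-accumulate counts) for standard encoder backbones.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff
Config/testthat/edition: 3
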