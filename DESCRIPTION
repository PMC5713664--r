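Package: gmidemons
Title: Multimodal Deformable Image Registration with Mutual-Information
    Demons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deformable registration of multimodal medical image pairs
    (e.g. PET to CT) using the demons optical-flow algorithm augmented
    with an external force derived from the gradient of Parzen-window
    mutual information, embedded in a coarse-to-fine multiresolution
    pyramid with a rigid mutual-information pre-alignment stage.
    Includes Hausdorff-family evaluation metrics (including the modified
    Hausdorff distance), synthetic multimodal phantom generation with
    known ground-truth deformations, NIfTI and portable raw-array image
    I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
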