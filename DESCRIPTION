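Package: metaboscope
Title: Simulated Whole-Body Glucose Metabolism Quantification from
    FDG-PET/MRI, Clamp and OGTT Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify tissue and whole-body glucose metabolism in
    a two-arm weight-loss trial setting: irreversible two-tissue-compartment
    simulation of 18F-FDG kinetics and Patlak graphical estimation of the
    net influx rate Ki at region and voxel level; conversion to tissue
    glucose metabolic rates via lumped constants; hyperinsulinaemic-
    euglycaemic clamp quantification (M value per kg lean body mass);
    Dixon water-fat MRI fat-fraction maps, adipose segmentation and body
    volumes; fasting and OGTT glucose-homeostasis indices (HOMA-IR,
    Matsuda, insulinogenic, disposition); whole-body glucose disposal and
    endogenous glucose production; and the trial statistical layer
    (normality gating, geometric-mean summaries, paired and
    baseline-adjusted comparisons, Fisher's exact test). A synthetic
    cohort generator produces clamp traces, OGTT samples, FDG input
    functions and tissue time-activity curves, and voxel body phantoms
    with known ground truth, so the full pipeline runs without any real
    imaging or clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
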