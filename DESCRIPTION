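Package: marrowquant
Title: Quantitative CT and FDG-PET Bone-Marrow Assessment for Multiple Myeloma
Version: 0.1.0
Authors@R: person("Marrowquant", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying myelomatous bone-marrow involvement of the
    appendicular skeleton from low-dose CT and [18F]FDG PET volumes.
    Implements Hounsfield-unit tissue classification, the manual
    highest-mean-ROI CT value (CTv), the semi-automated cumulative CT value
    (cCTv), SUV volume-of-interest statistics, rule-based IMPeTUs/Deauville
    scoring, liver-threshold metabolic tumor volume (MTV) and total lesion
    glycolysis (TLG), and the nonparametric cohort statistics used to relate
    imaging metrics to clinical covariates. A synthetic long-bone CT/PET
    phantom generator with known ground truth supports validation and
    simulation studies in place of patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
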