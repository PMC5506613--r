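Package: eitsbt
Title: Electrical Impedance Tomography Analysis of Spontaneous Breathing Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline analysis of electrical impedance tomography (EIT) frame
    sequences recorded around spontaneous breathing trials in ventilator
    weaning. Provides cardiac-frequency low-pass filtering, breath-cycle
    segmentation of the global impedance curve, and the functional-EIT index
    set used to quantify regional ventilation: tidal impedance variation
    (TIV), end-expiratory lung impedance change (dEELI), ventral-to-dorsal
    impedance ratio (IR, with patient-adapted regions of interest), the
    global inhomogeneity index (GI), the regional ventilation delay index
    under spontaneous breathing (spRVD), and an EIT-derived rapid shallow
    breathing index. A synthetic-thorax phantom and virtual-cohort generator
    with analytic ground truth support verification by parameter recovery,
    and a ROC module evaluates baseline GI as a predictor of ventilatory
    deterioration after a T-piece trial.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
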