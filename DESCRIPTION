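Package: gelphantom
Title: Design and In Silico Validation of Tunable MRI Phantom Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing tissue-mimicking hydrogel test materials for
    quantitative MRI at 3 Tesla. Forward models link Gd-DTPA, agarose, and soy
    lecithin concentrations to T1, T2, and the apparent diffusion coefficient
    (ADC); a three-step inverse solver turns target (T1, T2, ADC) triples into
    gel recipes; feasibility analysis maps the achievable parameter space.
    A synthetic MR acquisition module (inversion-recovery, CPMG, and
    diffusion-weighted imaging over a tube phantom layout) and voxel-wise
    parametric mapping support simulate-then-fit validation of recipes with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    RNifti,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
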