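Package: phagebuilder
Title: Building and Validating Phage Virion Models from Predicted Subcomplexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-prediction assembly and validation of complete phage virion
    atomic models from structure-predictor subcomplexes. Provides confidence
    gating on per-residue pLDDT profiles and predicted-aligned-error (PAE)
    matrices, least-squares rigid superposition (Kabsch), the
    truncate/predict/graft procedure for oligomers beyond the predictor's
    size limit, stacked-ring extension of tail tubes, sequential composition
    of virion sections, cyclic-symmetry axis fitting, Shrake-Rupley solvent
    accessible surface areas and buried interface areas, and
    cross-correlation fitting of atomic models into low-resolution EM density
    maps including a map hand-flip search. A synthetic-data generator builds
    ground-truth ring, tube, confidence and map fixtures so the whole
    pipeline is testable without any prediction run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
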