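Package: toccsl
Title: Single-Molecule Oligomer Stoichiometry and Transporter Kinetics
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying membrane-transporter oligomerization
    and function from single-molecule fluorescence microscopy and
    functional assays: TOCCSL (thinning out clusters while conserving
    stoichiometry of labeling) brightness-distribution deconvolution by
    autoconvolution mixture fitting with bootstrap uncertainties, FRAP
    mobile-fraction estimation by one-phase association fitting,
    normalized sensitized-emission FRET with spectral bleed-through
    correction, Michaelis-Menten uptake, one-site binding, turnover
    rates, efflux normalization and whole-cell patch-clamp kinetics
    summaries, together with a synthetic-data generator that produces
    ground-truth-annotated image stacks, traces and assay tables so
    every analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
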