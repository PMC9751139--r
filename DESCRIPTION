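Package: stimmap
Title: Mapping Deep Brain Stimulation Outcomes at Fiber, Voxel and Network Level
Version: 0.1.0
Authors@R:
    person("Stimmap", "Developers", email = "stimmap@example.org", role = c("aut", "cre"))
Description: A three-level analysis pipeline for probabilistic mapping of deep
    brain stimulation (DBS) outcomes from per-patient electric-field models:
    streamline-level fiber filtering (per-tract Spearman correlation between
    peak E-field weights and clinical improvement), voxel-level sweetspot and
    sourspot mapping with cluster extraction, and normative-connectome network
    mapping with connectivity fingerprints and R-map models.  Includes
    score-based outcome estimation, leave-one-out and k-fold cross-validation,
    permutation testing, Benjamini-Hochberg corrected binary-event (flashback)
    fiber contrasts, a closed-form point-source E-field simulator, NIfTI-1 and
    TRK/TCK streamline I/O, and a fully seeded synthetic-cohort generator with
    planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
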