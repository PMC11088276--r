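Package: polyqscreen
Title: High-Content Screening and Validation Statistics for Suppressors of
    PolyQ Toxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of the quantitative cascade used to
    discover and validate small-molecule suppressors of polyglutamine
    (Htt-Q94) toxicity in an inducible cell model: nuclei counting from
    nuclear-stain images, per-plate percent-of-control normalization of
    384-well screens, 3-SD hit calling against dox-only controls with Z'
    quality control, multi-dose validation by ANOVA with Dunnett contrasts,
    transcriptional signature extraction and Connectivity-Map-style
    drug matching with class enrichment, and downstream phenotype
    statistics (growth-competition relative fitness, per-cell organelle
    intensity, embryo survival, nematode motility). Every input can be
    produced by seeded synthetic-data generators that carry a parallel
    ground-truth record, so the whole pipeline is exercisable and testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    multcomp,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
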