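Package: aeval
Title: Evaluation and Retrieval Toolkit for Medical-Device Adverse-Event
    Report Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for scoring and stress-testing automated
    analysis of medical-device adverse-event reports (infant incubators as
    the worked domain). Implements hierarchical exact/fuzzy element
    matching with an edit-distance threshold, the element recall rate, an
    information-density index with a redundancy and terminology-error
    correction factor, risk recall over a six-item safety list, and the
    comparative arithmetic used to summarise model improvements.
    Calibration utilities provide intraclass correlation, Pearson
    correlation, Cohen's kappa, a penalty-weight grid search against
    simulated expert scores, and an annotation quality-control gate.
    A micro-transformer harness exercises dual-adapter parameter-efficient
    fine-tuning (low-rank adaptation on attention query/value projections
    plus activation-scaling vectors on feed-forward layers) with a
    3:1 mixed-domain objective and a two-stage transfer schedule.
    A supervised contrastive (InfoNCE) fine-tuning loop adapts a toy
    character n-gram embedder for clause retrieval, and a retrieval
    scaffold supplies clause-aware chunking, cosine-threshold search,
    constrained prompt construction and answer citation auditing. Seeded
    synthetic generators produce every input with ground truth attached.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
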