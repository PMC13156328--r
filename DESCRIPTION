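Package: orqa
Title: Operating-Room Question-Answering Benchmark Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for constructing and scoring multimodal operating-room
    (OR) question-answering benchmarks. Provides a seeded simulator of
    synthetic OR scene timelines whose annotation structure mirrors four
    families of public OR datasets (multi-view boxes, 3D positions, scene
    graphs, clinical roles, surgical phases, gaze, robot state logs,
    sterility flags, monitor text, speech transcripts), a template engine
    that derives question-answer pairs for 23 clinical tasks, a
    diversity-aware sampler based on inverse question and answer frequency
    with per-source mixing weights, the complete ORQA Score evaluation
    suite (tiered box IoU, relative-error bands, set IoU, macro F1,
    normalized Levenshtein, BLEU-1) with nonparametric bootstrap
    confidence intervals, a most-frequent-answer statistical baseline with
    a lenient free-text answer parser, and a temperature-scaled
    knowledge-distillation kernel with top-left weight-crop initialization
    and progressive shrinking, exercised on toy networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
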