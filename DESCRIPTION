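Package: ehrdx
Title: Multi-Task Transformer Classification of Clinical Diagnoses from
    Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end framework for automated diagnosis classification
    from electronic health record (EHR) text and structured metadata. It
    couples a Transformer text encoder with a diagnostic-relevance attention
    bias and medical-concept pooling, a gated multimodal multi-task learning
    head with a learned task-relationship matrix and importance-weighted
    losses, and parameter-efficient transfer learning via bottleneck
    adapters, domain-confusion training, a curriculum schedule and knowledge
    distillation. Includes a reproducible synthetic clinical-corpus
    generator with controllable inter-task label correlation and domain
    shift, deterministic clinical text preprocessing (abbreviation
    expansion, concept recognition, negation and temporal cues), evaluation
    metrics, and ablation, robustness and temporal-split harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
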