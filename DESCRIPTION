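Package: dxbert
Title: Denoised Diagnosis-Sequence Modelling with Comorbidity Embeddings and a Compact BERT Encoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning tabular electronic medical records into aligned
    diagnosis, visit and time-interval sequences, mining trigger/target
    comorbidities and building a weighted comorbidity graph with random-walk
    skip-gram disease embeddings, filtering noise diagnoses (influenza-like
    illnesses by default) with a semi-supervised double-attention denoiser,
    and pretraining/fine-tuning a compact BERT-style encoder on masked-code
    and trigger/target next-sentence objectives to predict whether a target
    disease appears within a fixed horizon. Includes a synthetic-cohort
    generator emulating the revisit-interval structure of claims data so the
    whole pipeline is testable without access-restricted registries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
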