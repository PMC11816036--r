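Package: nextvisit
Title: Next-Visit Token-Prediction Heads for Coded Patient Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reformulates disease-onset prediction from coded electronic
    health record trajectories as token prediction over a BERT-style
    encoder. Provides a synthetic coded-visit cohort generator, a
    fixed-length sequence codec with next-visit [MASK] insertion, a small
    transformer encoder with token and visit embeddings, masked-code
    pretraining with weight tying, three interchangeable prediction heads
    (binary classification, token prediction on the pooled patient vector,
    and masked-token prediction at the appended next-visit position),
    recurrent and logistic-regression baselines, and a few-shot
    learning-curve harness evaluated by AUROC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    glmnet,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    MASS
Config/testthat/edition: 3
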