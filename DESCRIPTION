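Package: lesionnav
Title: Multi-Agent Reinforcement Learning for Spatiotemporal Skin Lesion Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-navigation diagnosis of dermoscopic skin lesions with
    cooperative multi-agent Q-learning. A spatial agent inspects 64x64
    image patches on a stride-32 grid and a temporal/text agent encodes
    rule-based lesion descriptors with a bidirectional recurrent network;
    their action values are fused by Value Decomposition Networks (VDN)
    and trained with centralized-training/decentralized-execution
    Q-learning (experience replay, target networks, epsilon-greedy
    exploration). Includes a seeded synthetic dermoscopy generator with
    3-step pseudo-sequences (gradual area growth and darkening), fusion
    and backbone ablation variants, and a clinical evaluation layer:
    confusion-matrix metrics, ROC/AUC, stratified cross-validation,
    one-way ANOVA with Tukey HSD, and decision-curve analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
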