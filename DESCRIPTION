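Package: descvae
Title: Descriptor-Guided SMILES Variational Autoencoders for QSAR/QSPR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Joint pre-training of SMILES variational autoencoders (a
    convolutional-encoder chemical VAE and a GRU-based penalized VAE) with
    auxiliary molecular-descriptor predictor heads, together with the
    surrounding QSAR/QSPR machinery: dataset curation (canonicalization,
    InChIKey deduplication, salt and mixture removal), filter-based
    descriptor selection (variance threshold, Pearson correlation ranking,
    inter-correlation pruning), embedding extraction, downstream property
    models (linear, multilayer perceptron, 1D residual network) under
    tenfold cross-validation, bootstrap model comparison, and latent-space
    diagnostics (expected-KL distance to the prior, linear probes, K-means
    cluster-error analysis, PCA projections). Includes a synthetic-fixture
    generator producing small valid SMILES corpora with planted
    descriptor-property structure so the full workflow runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
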