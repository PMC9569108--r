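# descvae

Descriptor-guided pre-training of SMILES variational autoencoders for
QSAR/QSPR modeling, with the full downstream evaluation stack.

## The problem

Property prediction for small molecules (aqueous solubility logS,
lipophilicity logD, blood–brain-barrier penetration logBB, ...) is usually
limited by labelled data. A standard remedy is transfer learning: pre-train
a SMILES variational autoencoder on a large unlabelled corpus and use its
latent codes as molecular features. `descvae` implements a targeted variant
of this idea: first select the few molecular descriptors most linearly
correlated with the downstream property (a filter pipeline: variance
threshold, Pearson ranking, inter-correlation pruning, top-k), then
pre-train the VAE **jointly with a predictor head** for those descriptors,

```
loss = reconstruction + beta * KL(q(z|x) || N(0, I)) + lambda * MSE(descriptors)
```

so the latent space is organized along property-relevant axes before the
downstream model ever sees it. Two architectures are provided: a
convolutional-encoder chemical VAE (`cvae`, 3-hidden-layer MLP head) and a
GRU-based penalized VAE (`pvae`, character-frequency-weighted
reconstruction loss, linear head).

Around that core the package implements, for audiences building or
auditing embedding-based QSAR models:

* curation (canonicalization, InChIKey deduplication with
  conflicting-label removal, salt/mixture exclusion, logBB binarization at
  −1),
* downstream models — linear/logistic, MLP, 1-D ResNet — under seeded
  tenfold cross-validation with R²/RMSE or accuracy/F1,
* an ECFP4 (1024-bit) fingerprint baseline,
* within-fold bootstrap significance comparison (1000 trials, 95% level),
* latent diagnostics: expected-KL distance of a dataset to the prior,
  linear probes of descriptor information, K-means cluster-error analysis,
  PCA projections,
* a synthetic-fixture generator (valid acyclic C/N/O SMILES with planted
  descriptor–property structure) so everything runs self-contained,
* a one-config workflow runner with JSON-lines manifests, and a thin CLI
  (`inst/cli/descvae`).

All neural components (GRU, 1-D convolutions, Adam) are implemented in
base R with hand-derived backpropagation, validated against numerical
gradients in the test suite.

## A worked example

Run the whole workflow on a generated 200-molecule fixture whose property
is planted on MolLogP:

```r
library(descvae)

cfg <- run_config(
  fixture = fixture_spec(200, 8, planted_descriptors = c(MolLogP = 1),
                         noise_sd = 0.5, seed = 5),
  vae = vae_config("pvae", latent_dim = 8, hidden_dim = 24, epochs = 10,
                   beta = 0.05, lambda_pred = 5, lr = 3e-3,
                   batch_size = 64),
  models = "linear", cluster_k = 4, seed = 31,
  out_dir = tempfile("descvae_run_"))

manifest <- run_workflow(cfg)
manifest
#> <run_manifest> 6 completed stages in /tmp/.../descvae_run_...
#>   preprocess           seed 316230         1.29s
#>   select_descriptors   seed 328891         0.07s
#>   pretrain             seed 314091         1.12s
#>   embed                seed 311734         0.01s
#>   qsar_cv              seed 313202         0.01s
#>   diagnose             seed 314059         0.07s

manifest$results$select_descriptors$top_k
#> [1] "MolLogP"       "NumHAcceptors" "TPSA"

manifest$results$qsar_cv$linear
#> <cv_result> linear (regression), 10-fold CV on 200 molecules
#>   r2        0.4373 +/- 0.1736
#>   rmse      0.8183 +/- 0.1705
```

The selection stage correctly ranks the planted descriptor (MolLogP)
first; the linear model on 8-dimensional embeddings from a 10-epoch VAE
recovers a sizeable fraction of the planted signal (cross-validated
R² ≈ 0.44; the fixture's noise floor and the tiny training budget bound
what is reachable). The diagnostics stage reports per-cluster KL distance
and RMSE plus the source-corpus distance to the prior. Re-running with the
same config reproduces every stage's artifacts bit-identically.

See `vignette("descvae-methods")` for the model, its assumptions, and the
reasoning behind the numerical choices.

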