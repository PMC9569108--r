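# Shared fixtures, built in code and memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

small_corpus <- function(n = 30, seed = 3) {
  cached(paste0("corpus_", n, "_", seed),
         generate_corpus(fixture_spec(n, 7, seed = seed)))
}

small_dataset <- function(n = 30, seed = 3) {
  cached(paste0("dataset_", n, "_", seed), {
    ds <- mol_dataset_from_smiles(small_corpus(n, seed))
    remove_salts_and_mixtures(deduplicate(ds))
  })
}

small_descriptors <- function(n = 30, seed = 3) {
  cached(paste0("desc_", n, "_", seed),
         compute_descriptors(small_dataset(n, seed)))
}

# synthetic latent embedding with well-separated posterior blobs; used to
# exercise the diagnostics without training a model
blob_embedding <- function(n_per = 30, k = 5, far_radius = 6, dim = 4,
                           seed = 99) {
  set.seed(seed)
  centers <- matrix(rnorm(k * dim, 0, 0.5), k, dim)
  centers[k, ] <- far_radius / sqrt(dim)  # one blob far from the prior
  mu <- do.call(rbind, lapply(seq_len(k), function(b) {
    sweep(matrix(rnorm(n_per * dim, 0, 0.15), n_per, dim), 2,
          centers[b, ], "+")
  }))
  structure(list(vectors = mu, posterior_means = mu,
                 posterior_logvars = mu * 0, mode = "mean",
                 seed = NA_integer_),
            class = "vae_embedding")
}
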