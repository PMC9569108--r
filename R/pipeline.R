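# End-to-end workflow: preprocess -> select descriptors -> pretrain VAE
# (with or without the predictor head) -> embed -> QSAR CV -> compare /
# diagnose, driven by a single config with per-stage seeds and a JSON-lines
# run manifest.

# per-stage seed derived deterministically from the global seed and the
# stage name, kept below 2^31
.stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(global_seed) * 10007L + h) %% 2147483647L
}

#' Workflow configuration
#'
#' @param target_csv Path to the labelled target CSV (or `NULL` to generate
#'   a synthetic fixture from `fixture`).
#' @param smiles_column,label_column,task_type Target-file schema.
#' @param source_smiles Optional path to a source-corpus SMILES file (one
#'   per line); defaults to the target molecules when omitted.
#' @param fixture Optional [fixture_spec()] used when no target file is
#'   given.
#' @param k,var_threshold,r_max Descriptor-selection parameters.
#' @param vae A [vae_config()]; its `lambda_pred` decides whether the
#'   predictor head is trained.
#' @param n_descriptors_joint How many selected descriptors feed the
#'   predictor head (0 disables joint training).
#' @param models Character vector of QSAR families to run.
#' @param n_folds CV folds.
#' @param cluster_k Clusters for the latent diagnostics.
#' @param seed Global seed; every stage derives its own from it.
#' @param out_dir Output directory for artifacts and the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(target_csv = NULL, smiles_column = "smiles",
                       label_column = "y",
                       task_type = c("regression", "classification"),
                       source_smiles = NULL, fixture = fixture_spec(),
                       k = 3L, var_threshold = 0.5, r_max = 0.9,
                       vae = vae_config(latent_dim = 16L, epochs = 30L),
                       n_descriptors_joint = 1L,
                       models = "linear", n_folds = 10L, cluster_k = 5L,
                       seed = 1L, out_dir = tempfile("descvae_run_")) {
  task_type <- match.arg(task_type)
  if (!is.null(target_csv) && !file.exists(target_csv)) {
    stop("target_csv does not exist: ", target_csv)
  }
  if (!is.null(source_smiles) && !file.exists(source_smiles)) {
    stop("source_smiles does not exist: ", source_smiles)
  }
  structure(list(target_csv = target_csv, smiles_column = smiles_column,
                 label_column = label_column, task_type = task_type,
                 source_smiles = source_smiles, fixture = fixture,
                 k = as.integer(k), var_threshold = var_threshold,
                 r_max = r_max, vae = vae,
                 n_descriptors_joint = as.integer(n_descriptors_joint),
                 models = models, n_folds = as.integer(n_folds),
                 cluster_k = as.integer(cluster_k),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Write / read a workflow config
#'
#' Round-trips through YAML: `read_run_config(write_run_config(cfg, path))`
#' reproduces an equal config.
#'
#' @param config A `run_config`.
#' @param path YAML path.
#' @return `path` / the `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lst <- unclass(config)
  lst$vae <- unclass(lst$vae)
  lst$fixture <- unclass(lst$fixture)
  # the yaml writer drops names of atomic vectors; keep the weight map
  lst$fixture$planted_descriptors <-
    as.list(lst$fixture$planted_descriptors)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$vae <- do.call(vae_config, lst$vae)
  lst$fixture <- if (!is.null(lst$fixture)) do.call(fixture_spec, lst$fixture)
  do.call(run_config, lst)
}

.manifest_add <- function(manifest_path, stage, outputs, seed, t0) {
  hashes <- lapply(outputs, function(f) {
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  })
  rec <- list(stage = stage, outputs = as.list(outputs),
              md5 = hashes, seed = seed,
              wall_time_s = round(as.numeric(Sys.time()) - t0, 3))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = manifest_path, append = TRUE)
  rec
}

#' Run the full workflow
#'
#' Executes preprocess, descriptor selection, VAE pre-training, embedding,
#' QSAR cross-validation and latent diagnostics in order, writing each
#' stage's artifact and a JSON-lines manifest (stage, output hashes, seed,
#' wall time) under `config$out_dir`. Deterministic stages re-run
#' bit-identically under the same config.
#'
#' @param config A [run_config()].
#' @return A `run_manifest` list with the in-memory stage results and the
#'   manifest records.
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out, "manifest.jsonl")
  if (file.exists(manifest_path)) file.remove(manifest_path)
  records <- list()
  results <- list()
  stage <- function(name, code) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(code, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    records[[name]] <<- .manifest_add(manifest_path, name, res$outputs,
                                      res$seed, t0)
    results[[name]] <<- res$value
    res$value
  }

  # 1. preprocess -----------------------------------------------------
  pre <- stage("preprocess", {
    seed <- .stage_seed(config$seed, "preprocess")
    if (is.null(config$target_csv)) {
      fx <- config$fixture
      fx$seed <- seed %% 1000000L
      fixture <- make_fixture(fx)
      dataset <- fixture$dataset
      desc <- fixture$descriptors
    } else {
      dataset <- load_dataset(config$target_csv, config$smiles_column,
                              config$label_column, config$task_type)
      dataset <- remove_salts_and_mixtures(deduplicate(dataset))
      desc <- compute_descriptors(dataset)
    }
    clean_csv <- file.path(out, "clean.csv")
    write_dataset(dataset, clean_csv, file.path(out, "curation.json"))
    utils::write.csv(as.data.frame(desc), file.path(out, "desc.csv"),
                     row.names = FALSE)
    list(value = list(dataset = dataset, desc = desc), seed = seed,
         outputs = c(clean_csv, file.path(out, "curation.json"),
                     file.path(out, "desc.csv")))
  })

  dataset <- pre$dataset
  desc <- pre$desc
  kept <- attr(desc, "kept")
  y <- dataset$label[kept]
  smiles <- dataset$canonical_smiles[kept]

  # 2. descriptor selection -------------------------------------------
  sel <- stage("select_descriptors", {
    seed <- .stage_seed(config$seed, "select_descriptors")
    res <- select_descriptors(desc, y, var_threshold = config$var_threshold,
                              r_max = config$r_max, k = config$k)
    sel_json <- file.path(out, "selection.json")
    jsonlite::write_json(list(
      selected = res$top_k, ranking = res$ranking,
      removed_low_variance = res$removed_low_variance,
      removed_intercorrelated = res$removed_intercorrelated),
      sel_json, auto_unbox = TRUE, digits = NA)
    list(value = res, seed = seed, outputs = sel_json)
  })

  # 3. pretrain --------------------------------------------------------
  model <- stage("pretrain", {
    seed <- .stage_seed(config$seed, "pretrain")
    corpus <- if (!is.null(config$source_smiles)) {
      canon <- canonicalize_smiles(readLines(config$source_smiles))
      canon[!is.na(canon)]
    } else {
      smiles
    }
    vcfg <- config$vae
    vcfg$seed <- seed %% 1000000L
    joint_names <- utils::head(sel$top_k, config$n_descriptors_joint)
    dtab <- NULL
    if (length(joint_names) > 0 && vcfg$lambda_pred > 0) {
      corpus_ds <- mol_dataset_from_smiles(corpus)
      corpus_desc <- compute_descriptors(corpus_ds, joint_names)
      ck <- attr(corpus_desc, "kept")
      corpus <- corpus_ds$canonical_smiles[ck]
      dtab <- corpus_desc
    }
    m <- train_vae(vcfg, corpus, descriptor_table = dtab)
    mdir <- file.path(out, "model")
    save_vae(m, mdir)
    list(value = m, seed = seed,
         outputs = file.path(mdir, c("config.yaml", "vocab.json",
                                     "standardization.json")))
  })

  # 4. embed ------------------------------------------------------------
  emb <- stage("embed", {
    seed <- .stage_seed(config$seed, "embed")
    e <- embed_molecules(model, smiles, mode = "mean")
    emb_csv <- file.path(out, "embeddings.csv")
    utils::write.csv(e$vectors, emb_csv, row.names = FALSE)
    list(value = e, seed = seed, outputs = emb_csv)
  })

  # 5. qsar cross-validation --------------------------------------------
  cv <- stage("qsar_cv", {
    seed <- .stage_seed(config$seed, "qsar_cv")
    res <- lapply(config$models, function(fam) {
      sp <- model_spec(fam, config$task_type, seed = seed %% 1000000L)
      r <- run_cv(sp, emb$vectors, y, n_folds = config$n_folds,
                  seed = seed %% 1000000L)
      write_cv_result(r, file.path(out, paste0("cv_", fam, ".json")))
      r
    })
    names(res) <- config$models
    list(value = res, seed = seed,
         outputs = file.path(out, paste0("cv_", config$models, ".json")))
  })

  # 6. diagnostics -------------------------------------------------------
  stage("diagnose", {
    seed <- .stage_seed(config$seed, "diagnose")
    first_cv <- cv[[1L]]
    diag <- cluster_error_analysis(
      emb, first_cv$predictions, y, k = config$cluster_k,
      seed = seed %% 1000000L,
      source_distance = dataset_prior_distance(model, smiles))
    pca <- pca_project(emb, 2L)
    diag_json <- file.path(out, "diagnostics.json")
    jsonlite::write_json(list(
      clusters = diag$clusters, source_distance = diag$source_distance,
      pca_explained_variance = pca$explained_variance),
      diag_json, auto_unbox = TRUE, digits = NA)
    list(value = list(clusters = diag, pca = pca), seed = seed,
         outputs = diag_json)
  })

  structure(list(config = config, results = results, records = records,
                 manifest_path = manifest_path),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> ", length(x$records), " completed stages in ",
      x$config$out_dir, "\n", sep = "")
  for (r in x$records) {
    cat(sprintf("  %-20s seed %-12s %6.2fs\n", r$stage,
                format(r$seed), r$wall_time_s))
  }
  invisible(x)
}

#' Two-level variance decomposition of embedding-based QSAR models
#'
#' Reproduces the repeated-embeddings versus repeated-pre-trainings
#' decomposition: the aggregate CV metric's spread across `n_embeddings`
#' sampled encodings of one fixed model, and across `n_pretrainings` models
#' trained from fresh seeds (one embedding each).
#'
#' @param config A [run_config()] (its `models[1]` family is used).
#' @param n_pretrainings Number of independently trained VAEs.
#' @param n_embeddings Number of sampled embeddings of the first VAE.
#' @param embedding_mode `"sample"` (default) or `"mean"`; with `"mean"`
#'   the embedding level is deterministic and its SD is zero.
#' @return A `variance_report` list with the per-run scores and the mean/SD
#'   at both levels.
#' @export
experiment_variance <- function(config, n_pretrainings = 3L,
                                n_embeddings = 3L,
                                embedding_mode = c("sample", "mean")) {
  stopifnot(inherits(config, "run_config"),
            n_pretrainings >= 1, n_embeddings >= 1)
  embedding_mode <- match.arg(embedding_mode)
  base <- run_workflow(config)
  dataset <- base$results$preprocess$dataset
  desc <- base$results$preprocess$desc
  kept <- attr(desc, "kept")
  y <- dataset$label[kept]
  smiles <- dataset$canonical_smiles[kept]
  sel <- base$results$select_descriptors
  fam <- config$models[[1L]]
  metric_name <- if (config$task_type == "regression") "r2" else "accuracy"
  score_of <- function(vectors, seed) {
    sp <- model_spec(fam, config$task_type, seed = seed)
    r <- run_cv(sp, vectors, y, n_folds = config$n_folds, seed = seed)
    r$aggregate$mean[r$aggregate$metric == metric_name]
  }
  # level 1: repeated embeddings of the fixed pre-trained model
  model <- base$results$pretrain
  emb_scores <- vapply(seq_len(n_embeddings), function(i) {
    e <- embed_molecules(model, smiles, mode = embedding_mode, seed = i)
    score_of(e$vectors, seed = 1L)
  }, numeric(1))
  # level 2: repeated pre-trainings, one embedding each
  pre_scores <- vapply(seq_len(n_pretrainings), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    cfg_i$out_dir <- file.path(config$out_dir, paste0("pretrain_rep_", i))
    run_i <- run_workflow(cfg_i)
    e <- embed_molecules(run_i$results$pretrain, smiles,
                         mode = embedding_mode, seed = 1L)
    score_of(e$vectors, seed = 1L)
  }, numeric(1))
  structure(list(
    metric = metric_name,
    embedding_scores = emb_scores,
    pretraining_scores = pre_scores,
    embedding_mean = mean(emb_scores),
    embedding_sd = if (embedding_mode == "mean") 0 else stats::sd(emb_scores),
    pretraining_mean = mean(pre_scores),
    pretraining_sd = stats::sd(pre_scores),
    n_cv_runs = n_embeddings + n_pretrainings),
    class = "variance_report")
}

#' @export
print.variance_report <- function(x, ...) {
  cat("<variance_report> metric = ", x$metric, "\n", sep = "")
  cat(sprintf("  repeated embeddings    : mean %.4f, sd %.4f (n = %d)\n",
              x$embedding_mean, x$embedding_sd, length(x$embedding_scores)))
  cat(sprintf("  repeated pre-trainings : mean %.4f, sd %.4f (n = %d)\n",
              x$pretraining_mean, x$pretraining_sd,
              length(x$pretraining_scores)))
  invisible(x)
}
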