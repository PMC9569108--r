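# Self-contained synthetic fixtures: small valid SMILES corpora over acyclic
# C/N/O chemistry plus property vectors planted on computed descriptors.
# These stand in for a large source corpus and labelled target sets so the
# whole workflow runs without downloads.

# run code with a private RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.valence <- c(C = 4L, N = 3L, O = 2L)

#' Specification of a synthetic SMILES fixture
#'
#' @param n_molecules Number of distinct molecules to generate.
#' @param max_heavy_atoms Largest molecule size, in heavy atoms.
#' @param generator `"random_walk"` (random valence-respecting trees) or
#'   `"acyclic_enumeration"` (exhaustive enumeration then sampling; only
#'   practical for small `max_heavy_atoms`).
#' @param planted_descriptors Named numeric vector of descriptor weights for
#'   [plant_property()].
#' @param noise_sd Gaussian noise standard deviation of the planted property.
#' @param seed Integer seed; the fixture is a pure function of the spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_molecules = 200, max_heavy_atoms = 9,
                         generator = c("random_walk", "acyclic_enumeration"),
                         planted_descriptors = c(MolWt = 1),
                         noise_sd = 0.5, seed = 1L) {
  generator <- match.arg(generator)
  stopifnot(n_molecules >= 1, max_heavy_atoms >= 1)
  planted_descriptors <- unlist(planted_descriptors)
  structure(list(n_molecules = as.integer(n_molecules),
                 max_heavy_atoms = as.integer(max_heavy_atoms),
                 generator = generator,
                 planted_descriptors = planted_descriptors,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "fixture_spec")
}

# SMILES for a rooted tree: children in parentheses except the last
.tree_smiles <- function(el, children) {
  out <- character(length(el))
  build <- function(i) {
    ch <- children[[i]]
    if (!length(ch)) return(el[[i]])
    subs <- vapply(ch, build, character(1))
    if (length(subs) > 1L) {
      paste0(el[[i]],
             paste0("(", subs[-length(subs)], ")", collapse = ""),
             subs[length(subs)])
    } else {
      paste0(el[[i]], subs)
    }
  }
  build(1L)
}

# one random valence-respecting tree over C/N/O
.random_tree_smiles <- function(n_atoms) {
  els <- character(n_atoms)
  free <- integer(n_atoms)
  children <- vector("list", n_atoms)
  pick <- function() sample(c("C", "N", "O"), 1L, prob = c(0.6, 0.2, 0.2))
  els[1] <- pick()
  free[1] <- .valence[[els[1]]]
  if (n_atoms > 1L) {
    for (i in 2:n_atoms) {
      open <- which(free[seq_len(i - 1L)] > 0L)
      if (!length(open)) break
      p <- if (length(open) == 1L) open else sample(open, 1L)
      els[i] <- pick()
      free[i] <- .valence[[els[i]]] - 1L
      free[p] <- free[p] - 1L
      children[[p]] <- c(children[[p]], i)
    }
  }
  used <- nzchar(els)
  .tree_smiles(els[used], children[used])
}

# exhaustive enumeration of acyclic single-bonded C/N/O molecules
.enumerate_acyclic <- function(max_heavy) {
  # subtree strings with n atoms whose root keeps one bond for its parent
  memo <- new.env(parent = emptyenv())
  compositions <- function(m, k, max_part) {
    # unordered compositions of m into at most k parts, parts non-increasing
    if (m == 0L) return(list(integer(0)))
    if (k == 0L) return(list())
    out <- list()
    for (first in seq_len(min(m, max_part))) {
      for (rest in compositions(m - first, k - 1L, first)) {
        out[[length(out) + 1L]] <- c(first, rest)
      }
    }
    out
  }
  subtrees <- function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- character(0)
    for (a in names(.valence)) {
      slots <- .valence[[a]] - 1L
      for (comp in compositions(n - 1L, slots, n - 1L)) {
        choice_sets <- lapply(comp, subtrees)
        grids <- do.call(expand.grid,
                         c(choice_sets, stringsAsFactors = FALSE))
        if (nrow(grids) == 0L && length(comp) == 0L) {
          out <- c(out, a)
        } else if (nrow(grids) > 0L) {
          subs <- as.matrix(grids)
          branch <- apply(subs, 1L, function(s) {
            k <- length(s)
            if (k > 1L) {
              paste0(paste0("(", s[-k], ")", collapse = ""), s[k])
            } else {
              s
            }
          })
          out <- c(out, paste0(a, branch))
        }
      }
    }
    memo[[key]] <- unique(out)
    memo[[key]]
  }
  raw <- unlist(lapply(seq_len(max_heavy), subtrees))
  unique(raw)
}

#' Generate a synthetic SMILES corpus
#'
#' All generated SMILES are valid, canonical and mutually distinct;
#' generation is a deterministic function of the spec (including its seed).
#'
#' @param spec A [fixture_spec()].
#' @return Character vector of `n_molecules` canonical SMILES.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    if (spec$generator == "acyclic_enumeration") {
      cand <- .enumerate_acyclic(spec$max_heavy_atoms)
      canon <- unique(canonicalize_smiles(cand))
      canon <- canon[!is.na(canon)]
      if (spec$n_molecules > length(canon)) {
        stop("capacity error: only ", length(canon),
             " distinct molecules exist up to ", spec$max_heavy_atoms,
             " heavy atoms; ", spec$n_molecules, " requested")
      }
      sort(sample(canon, spec$n_molecules))
    } else {
      canon <- character(0)
      rounds <- 0L
      m <- min(spec$max_heavy_atoms, 4L)
      while (length(canon) < spec$n_molecules && rounds < 50L) {
        rounds <- rounds + 1L
        batch_n <- max(2L * (spec$n_molecules - length(canon)), 32L)
        sizes <- sample(m:spec$max_heavy_atoms, batch_n, replace = TRUE)
        raw <- vapply(sizes, .random_tree_smiles, character(1))
        cb <- canonicalize_smiles(unique(raw))
        cb <- cb[!is.na(cb)]
        canon <- c(canon, setdiff(cb, canon))
      }
      if (length(canon) < spec$n_molecules) {
        stop("capacity error: could not generate ", spec$n_molecules,
             " distinct molecules with max_heavy_atoms = ",
             spec$max_heavy_atoms)
      }
      canon[seq_len(spec$n_molecules)]
    }
  })
}

#' Append planted synthetic descriptor columns
#'
#' Adds independent Gaussian columns (tagged `source = "planted"`) to a
#' descriptor table, optionally matched in location and scale to an
#' existing computed column. Computed descriptors of very small acyclic
#' molecules are strongly collinear (size, heteroatom content and
#' lipophilicity nearly span them), so identifiable planted-recovery
#' fixtures use dedicated planted columns instead of re-using computed
#' ones.
#'
#' @param table A `desc_table` or data frame.
#' @param names Names of the new planted columns.
#' @param seed Integer seed for the draws.
#' @param match Optional character vector (recycled) of computed columns
#'   whose mean and standard deviation the planted columns mimic.
#' @return The table with the new columns; the `source` attribute marks
#'   them `"planted"`.
#' @export
add_planted_columns <- function(table, names, seed = 1L, match = NULL) {
  stopifnot(length(names) >= 1)
  if (any(names %in% colnames(table))) {
    stop("column(s) already present: ",
         paste(intersect(names, colnames(table)), collapse = ", "))
  }
  n <- nrow(table)
  src <- attr(table, "source")
  if (is.null(src)) {
    src <- stats::setNames(rep("computed", ncol(table)), colnames(table))
  }
  cols <- with_seed(seed, {
    lapply(seq_along(names), function(i) {
      x <- stats::rnorm(n)
      if (!is.null(match)) {
        m <- table[[match[[(i - 1L) %% length(match) + 1L]]]]
        x <- x * stats::sd(m) + mean(m)
      }
      x
    })
  })
  for (i in seq_along(names)) table[[names[[i]]]] <- cols[[i]]
  attr(table, "source") <- c(src, stats::setNames(rep("planted",
                                                      length(names)),
                                                  names))
  table
}

#' Plant a property on a descriptor table
#'
#' Builds `y = sum_d w_d * standardize(d) + noise`, the linear
#' descriptor-property structure the descriptor-selection filter assumes.
#' With independent standardized descriptors the population correlation of
#' descriptor `d` with `y` is `w_d / sqrt(sum(w^2) + noise_sd^2)`.
#'
#' @param table A `desc_table` (or plain data frame of numeric columns).
#' @param weights Named numeric vector; names must be columns of `table`.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed for the noise draw.
#' @return Numeric property vector of length `nrow(table)`.
#' @export
plant_property <- function(table, weights, noise_sd = 0.5, seed = 1L) {
  missing <- setdiff(names(weights), names(table))
  if (length(missing)) {
    stop("unknown descriptor(s) in weights: ", paste(missing, collapse = ", "))
  }
  n <- nrow(table)
  y <- numeric(n)
  for (nm in names(weights)) {
    y <- y + weights[[nm]] * as.numeric(scale(table[[nm]]))
  }
  with_seed(seed, y + stats::rnorm(n, 0, noise_sd))
}

#' Build a complete labelled fixture
#'
#' Generates a corpus, curates it into a `mol_dataset`, computes descriptors
#' and plants the property from the spec. Optionally writes `corpus.smi`,
#' `clean.csv` and `desc.csv` under `out_dir`.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Optional output directory.
#' @return List with `corpus`, `dataset` (labelled `mol_dataset`),
#'   `descriptors` (`desc_table`) and `y`.
#' @export
make_fixture <- function(spec, out_dir = NULL) {
  corpus <- generate_corpus(spec)
  dataset <- mol_dataset_from_smiles(corpus, task_type = "regression",
                                     name = "synthetic-fixture")
  dataset <- remove_salts_and_mixtures(deduplicate(dataset))
  desc <- compute_descriptors(dataset)
  novel <- setdiff(names(spec$planted_descriptors), colnames(desc))
  if (length(novel)) {
    desc <- add_planted_columns(desc, novel, seed = spec$seed + 2L,
                                match = "MolLogP")
  }
  y <- plant_property(desc, spec$planted_descriptors, spec$noise_sd,
                      seed = spec$seed + 1L)
  dataset$label <- NA_real_
  dataset$label[attr(desc, "kept")] <- y
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(corpus, file.path(out_dir, "corpus.smi"))
    write_dataset(dataset, file.path(out_dir, "clean.csv"))
    utils::write.csv(as.data.frame(desc), file.path(out_dir, "desc.csv"),
                     row.names = FALSE)
  }
  list(corpus = corpus, dataset = dataset, descriptors = desc, y = y)
}
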