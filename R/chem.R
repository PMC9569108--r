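# Dataset curation: canonicalization, structure keys, deduplication,
# salt/mixture removal, label binarization, descriptor computation.
# Chemistry goes through Open Babel; everything else is base R.

# run obabel on a batch of "SMILES title" lines; parse failures are skipped
# (-e) and their titles simply absent from the output
.obabel <- function(lines, args) {
  if (Sys.which("obabel") == "") stop("obabel executable not found on PATH")
  f <- tempfile(fileext = ".smi")
  on.exit(unlink(f))
  writeLines(lines, f)
  out <- suppressWarnings(
    system2("obabel", c(f, args, "-e"), stdout = TRUE, stderr = FALSE))
  out[nzchar(out)]
}

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to the toolkit's canonical form. Strings the parser
#' rejects yield `NA`.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  ids <- paste0("m", seq_along(smiles))
  out <- .obabel(paste(smiles, ids), "-ocan")
  parts <- strsplit(out, "\t", fixed = TRUE)
  res <- rep(NA_character_, length(smiles))
  for (p in parts) {
    if (length(p) >= 2 && nzchar(p[[1]])) {
      idx <- match(trimws(p[[2]]), ids)
      if (!is.na(idx)) res[idx] <- p[[1]]
    }
  }
  res
}

#' Hashed structure keys (InChIKey)
#'
#' Computes the InChIKey for each molecule; identical structures map to
#' identical keys regardless of the SMILES spelling, which makes the key
#' suitable for duplicate detection.
#'
#' @param smiles Character vector of valid (ideally canonical) SMILES.
#' @return Character vector of InChIKeys, `NA` where conversion failed.
#' @export
structure_key <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  ok <- !is.na(smiles) & nzchar(smiles)
  res <- rep(NA_character_, length(smiles))
  if (any(ok)) {
    keys <- trimws(.obabel(smiles[ok], "-oinchikey"))
    if (length(keys) != sum(ok)) {
      stop("InChIKey conversion failed for ", sum(ok) - length(keys),
           " molecule(s)")
    }
    res[ok] <- keys
  }
  res
}

# mol_dataset constructor -------------------------------------------------

new_mol_dataset <- function(df, task_type, name, log = list()) {
  stopifnot(is.data.frame(df),
            all(c("raw_smiles", "canonical_smiles", "structure_key") %in%
                  names(df)))
  structure(df,
            task_type = task_type, dataset_name = name, curation_log = log,
            class = c("mol_dataset", "data.frame"))
}

.update_log <- function(dataset, entry) {
  log <- attr(dataset, "curation_log")
  attr(dataset, "curation_log") <- c(log, entry)
  dataset
}

#' @export
print.mol_dataset <- function(x, ...) {
  cat("<mol_dataset> ", attr(x, "dataset_name"), ": ", nrow(x),
      " molecules, task = ", attr(x, "task_type"), "\n", sep = "")
  log <- attr(x, "curation_log")
  if (length(log)) {
    for (nm in names(log)) cat("  ", nm, ": ", log[[nm]], "\n", sep = "")
  }
  if (nrow(x)) {
    print.data.frame(utils::head(as.data.frame(x), 5))
    if (nrow(x) > 5) cat("  ... ", nrow(x) - 5, " more rows\n", sep = "")
  }
  invisible(x)
}

#' Curation log of a molecule dataset
#'
#' @param dataset A `mol_dataset`.
#' @return Named list of per-rule removal counts accumulated so far.
#' @export
curation_log <- function(dataset) attr(dataset, "curation_log")

#' Load a molecular dataset from a delimited file
#'
#' Reads a CSV with a header row, canonicalizes the SMILES column, drops
#' unparseable rows (counted in the curation log), and attaches InChIKey
#' structure keys.
#'
#' @param path Path to a CSV file.
#' @param smiles_column Name of the SMILES column.
#' @param label_column Optional name of the property column.
#' @param task_type `"regression"` or `"classification"`. Classification
#'   labels must be (coercible to) 0/1.
#' @param name Dataset name used in printing and reports.
#' @return A `mol_dataset`: a data frame with columns `raw_smiles`,
#'   `canonical_smiles`, `structure_key` and (if labelled) `label`, plus a
#'   curation log attribute.
#' @export
load_dataset <- function(path, smiles_column, label_column = NULL,
                         task_type = c("regression", "classification"),
                         name = basename(path)) {
  task_type <- match.arg(task_type)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!smiles_column %in% names(df)) {
    stop("SMILES column '", smiles_column, "' not present in ", path)
  }
  label <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(df)) {
      stop("label column '", label_column, "' not present in ", path)
    }
    label <- df[[label_column]]
    if (task_type == "classification") {
      lab <- suppressWarnings(as.numeric(label))
      bad <- !is.na(lab) & !lab %in% c(0, 1)
      if (any(bad) || anyNA(lab[!is.na(label)])) {
        stop("classification labels must be 0/1; offending values: ",
             paste(utils::head(unique(label[bad | is.na(lab)]), 5),
                   collapse = ", "))
      }
      label <- lab
    } else {
      label <- suppressWarnings(as.numeric(label))
    }
  }
  mol_dataset_from_smiles(df[[smiles_column]], label = label,
                          task_type = task_type, name = name)
}

#' Build a dataset directly from SMILES strings
#'
#' @inheritParams load_dataset
#' @param smiles Character vector of raw SMILES.
#' @param label Optional numeric label vector aligned with `smiles`.
#' @return A `mol_dataset`; unparseable SMILES are dropped and counted.
#' @export
mol_dataset_from_smiles <- function(smiles, label = NULL,
                                    task_type = c("regression",
                                                  "classification"),
                                    name = "dataset") {
  task_type <- match.arg(task_type)
  canon <- canonicalize_smiles(smiles)
  keep <- !is.na(canon)
  df <- data.frame(raw_smiles = smiles[keep],
                   canonical_smiles = canon[keep],
                   structure_key = structure_key(canon[keep]),
                   stringsAsFactors = FALSE)
  if (!is.null(label)) df$label <- label[keep]
  rownames(df) <- NULL
  new_mol_dataset(df, task_type, name,
                  log = list(unparseable_removed = sum(!keep)))
}

#' Remove duplicate structures by structure key
#'
#' Groups records by InChIKey. A group whose labels agree (within `tolerance`
#' for regression; exactly for classification) keeps its first record; a
#' group with conflicting labels is removed entirely, treating the
#' measurements as contradictory.
#'
#' @param dataset A `mol_dataset`.
#' @param tolerance Maximum absolute label spread still considered agreement
#'   for regression tasks.
#' @return The deduplicated `mol_dataset` (log updated).
#' @export
deduplicate <- function(dataset, tolerance = 0.01) {
  stopifnot(inherits(dataset, "mol_dataset"))
  if (nrow(dataset) == 0L) return(dataset)
  key <- dataset$structure_key
  has_label <- "label" %in% names(dataset)
  keep_first <- !duplicated(key)
  conflicted <- rep(FALSE, nrow(dataset))
  if (has_label) {
    spl <- split(seq_len(nrow(dataset)), key)
    for (idx in spl) {
      if (length(idx) < 2L) next
      lab <- dataset$label[idx]
      lab <- lab[!is.na(lab)]
      if (length(lab) >= 2L) {
        spread <- max(lab) - min(lab)
        ok <- if (attr(dataset, "task_type") == "regression") {
          spread <= tolerance
        } else {
          spread == 0
        }
        if (!ok) conflicted[idx] <- TRUE
      }
    }
  }
  keep <- keep_first & !conflicted
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- new_mol_dataset(as.data.frame(out), attr(dataset, "task_type"),
                         attr(dataset, "dataset_name"),
                         attr(dataset, "curation_log"))
  .update_log(out, list(
    duplicates_removed = sum(!keep_first & !conflicted),
    conflicting_removed = sum(conflicted)
  ))
}

#' Exclude salts and mixtures
#'
#' Removes every record whose canonical SMILES contains more than one
#' covalently connected component (a `.` separator). Records are removed
#' whole; no largest-fragment rescue is attempted.
#'
#' @param dataset A `mol_dataset`.
#' @return The filtered `mol_dataset` (log updated).
#' @export
remove_salts_and_mixtures <- function(dataset) {
  stopifnot(inherits(dataset, "mol_dataset"))
  multi <- grepl(".", dataset$canonical_smiles, fixed = TRUE)
  out <- dataset[!multi, , drop = FALSE]
  rownames(out) <- NULL
  out <- new_mol_dataset(as.data.frame(out), attr(dataset, "task_type"),
                         attr(dataset, "dataset_name"),
                         attr(dataset, "curation_log"))
  .update_log(out, list(salts_mixtures_removed = sum(multi)))
}

#' Binarize blood-brain barrier partition values
#'
#' Compounds with `logBB >= threshold` are labelled BBB-penetrating
#' (class 1), the rest class 0.
#'
#' @param values Finite numeric vector of logBB values.
#' @param threshold Class boundary, included in the positive class.
#' @return Integer vector of 0/1 labels.
#' @export
binarize_logbb <- function(values, threshold = -1) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("logBB values must be finite numeric")
  }
  as.integer(values >= threshold)
}

# Descriptor registry ------------------------------------------------------

# Open Babel property names behind each registry descriptor; syntax-derived
# descriptors are counted from canonical SMILES tokens.
.ob_descriptor_map <- c(
  MolWt = "MW", MolLogP = "logP", TPSA = "TPSA", MolMR = "MR",
  NumHDonors = "HBD", NumHAcceptors = "HBA2", NumF = "nF"
)
.token_descriptors <- c("HeavyAtomCount", "NumHeteroatoms", "RingCount",
                        "NumAromaticRings")

#' Names of the available molecular descriptors
#'
#' @return Character vector of descriptor names accepted by
#'   [compute_descriptors()].
#' @export
descriptor_registry <- function() {
  c(names(.ob_descriptor_map), .token_descriptors)
}

#' Compute molecular descriptors for a dataset
#'
#' One numeric column per requested descriptor. Rows containing any
#' non-finite value are dropped and recorded; per-column |z| > `z_max`
#' outliers are flagged (and optionally dropped).
#'
#' @param dataset A non-empty `mol_dataset`.
#' @param descriptor_names Descriptors to compute (default: full registry,
#'   see [descriptor_registry()]).
#' @param drop_outliers If `TRUE`, rows flagged as outliers are dropped too.
#' @param z_max Per-column robust z-score threshold used for flagging.
#' @return A `desc_table`: data frame of descriptor columns with attributes
#'   `source` (per-column provenance tag), `kept` (logical vector over the
#'   dataset rows), `dropped_nonfinite`, `outlier_flags`.
#' @export
compute_descriptors <- function(dataset, descriptor_names = NULL,
                                drop_outliers = FALSE, z_max = 6) {
  stopifnot(inherits(dataset, "mol_dataset"))
  if (nrow(dataset) == 0L) stop("dataset is empty")
  if (is.null(descriptor_names)) descriptor_names <- descriptor_registry()
  unknown <- setdiff(descriptor_names, descriptor_registry())
  if (length(unknown)) {
    stop("unknown descriptor(s): ", paste(unknown, collapse = ", "))
  }
  smi <- dataset$canonical_smiles
  cols <- list()
  ob_wanted <- intersect(descriptor_names, names(.ob_descriptor_map))
  if (length(ob_wanted)) {
    ids <- paste0("m", seq_along(smi))
    prop_names <- unname(.ob_descriptor_map[ob_wanted])
    out <- .obabel(paste(smi, ids),
                   c("-osmi", "--append", shQuote(paste(prop_names,
                                                        collapse = " "))))
    fields <- strsplit(sub("^[^\t]*\t", "", out), " +")
    props <- matrix(NA_real_, length(smi), length(prop_names))
    for (fl in fields) {
      idx <- match(fl[[1]], ids)
      if (!is.na(idx) && length(fl) == length(prop_names) + 1L) {
        props[idx, ] <- suppressWarnings(as.numeric(fl[-1]))
      }
    }
    if (anyNA(props[, 1])) {
      stop("descriptor computation lost ", sum(is.na(props[, 1])),
           " molecule(s)")
    }
    for (j in seq_along(ob_wanted)) cols[[ob_wanted[j]]] <- props[, j]
  }
  tok_wanted <- intersect(descriptor_names, .token_descriptors)
  if (length(tok_wanted)) {
    toks <- smiles_tokens(smi)
    counts <- t(vapply(toks, .token_counts, numeric(4)))
    for (nm in tok_wanted) cols[[nm]] <- counts[, nm]
  }
  tab <- as.data.frame(cols[descriptor_names], optional = TRUE)
  names(tab) <- descriptor_names
  finite <- rowSums(!is.finite(as.matrix(tab))) == 0L
  tab_f <- tab[finite, , drop = FALSE]
  if (nrow(tab_f) > 1L) {
    z <- vapply(tab_f, function(x) {
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
    }, numeric(nrow(tab_f)))
    flags <- rowSums(abs(z) > z_max) > 0L
  } else {
    flags <- rep(FALSE, nrow(tab_f))
  }
  kept <- finite
  if (drop_outliers && any(flags)) {
    kept[which(finite)[flags]] <- FALSE
    tab_f <- tab_f[!flags, , drop = FALSE]
    flags <- flags[!flags]
  }
  rownames(tab_f) <- dataset$structure_key[kept]
  structure(tab_f,
            source = stats::setNames(rep("computed", ncol(tab_f)),
                                     names(tab_f)),
            kept = kept,
            dropped_nonfinite = sum(!finite),
            outlier_flags = flags,
            class = c("desc_table", "data.frame"))
}

#' @export
print.desc_table <- function(x, ...) {
  cat("<desc_table> ", nrow(x), " molecules x ", ncol(x), " descriptors (",
      attr(x, "dropped_nonfinite"), " rows dropped non-finite)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Write a cleaned dataset and its curation report
#'
#' @param dataset A `mol_dataset`.
#' @param path Output CSV path for the cleaned records.
#' @param report_path Optional JSON path for the per-rule removal counts.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, report_path = NULL) {
  stopifnot(inherits(dataset, "mol_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  if (!is.null(report_path)) {
    jsonlite::write_json(
      c(list(name = attr(dataset, "dataset_name"),
             task_type = attr(dataset, "task_type"),
             n_final = nrow(dataset)),
        attr(dataset, "curation_log")),
      report_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
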