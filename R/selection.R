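# Filter-based descriptor selection: variance threshold, Pearson ranking
# against the target, greedy inter-correlation pruning, top-k pick; plus the
# correlation-matched noisy-descriptor construction.

#' Remove low-variance descriptors
#'
#' Keeps exactly the columns whose sample variance exceeds `threshold`
#' (strict comparison: boundary variance is removed). Variance is taken on
#' raw, unstandardized values.
#'
#' @param table A `desc_table` or data frame of numeric columns.
#' @param threshold Variance threshold.
#' @return The filtered table; removed names in attribute
#'   `removed_low_variance`.
#' @export
variance_filter <- function(table, threshold = 0.5) {
  if (ncol(table) < 1L) stop("descriptor table has no columns")
  v <- vapply(as.data.frame(table), stats::var, numeric(1))
  keep <- is.finite(v) & v > threshold
  out <- table[, keep, drop = FALSE]
  attr(out, "removed_low_variance") <- names(v)[!keep]
  attr(out, "source") <- attr(table, "source")[keep]
  out
}

#' Rank descriptors by linear correlation with the target
#'
#' Pearson correlation of each column with `y`, ordered by decreasing
#' absolute value (alphabetical tie-break). An optional mask restricts the
#' computation to a labelled subset, as needed when only part of a
#' classification dataset carries numeric values.
#'
#' @param table Descriptor table.
#' @param y Numeric target, `length(y) == nrow(table)`.
#' @param mask Optional logical vector selecting the rows used.
#' @return A `corr_ranking`: data frame with columns `descriptor`,
#'   `pearson_r`, sorted by `|pearson_r|` descending.
#' @export
rank_by_target_correlation <- function(table, y, mask = NULL) {
  df <- as.data.frame(table)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), length(mask) == nrow(df))
    df <- df[mask, , drop = FALSE]
    y <- y[mask]
  }
  stopifnot(length(y) == nrow(df))
  if (stats::sd(y) == 0) stop("target is constant; correlation undefined")
  r <- vapply(df, function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  if (anyNA(r)) {
    warning("excluding constant descriptor(s): ",
            paste(names(r)[is.na(r)], collapse = ", "))
    r <- r[!is.na(r)]
  }
  ord <- order(-abs(r), names(r))
  structure(data.frame(descriptor = names(r)[ord],
                       pearson_r = unname(r[ord]),
                       stringsAsFactors = FALSE),
            target_name = "y",
            class = c("corr_ranking", "data.frame"))
}

#' Prune inter-correlated descriptors
#'
#' Greedy pass in ranking order: a descriptor is kept iff its absolute
#' pairwise Pearson correlation with every already-kept descriptor is at
#' most `r_max`, so the more task-correlated member of an offending pair
#' survives.
#'
#' @param ranking A `corr_ranking` from [rank_by_target_correlation()].
#' @param table The descriptor table the ranking was derived from.
#' @param r_max Pairwise absolute-correlation ceiling.
#' @return A `selection_result` list: `selected` (surviving names in ranking
#'   order), `ranking`, `removed_low_variance`,
#'   `removed_intercorrelated` (data frame dropped/kept/r).
#' @export
prune_intercorrelated <- function(ranking, table, r_max = 0.9) {
  stopifnot(inherits(ranking, "corr_ranking"))
  df <- as.data.frame(table)
  kept <- character(0)
  dropped <- data.frame(dropped = character(0), kept = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  for (nm in ranking$descriptor) {
    offending <- NULL
    for (k in kept) {
      r <- stats::cor(df[[nm]], df[[k]])
      if (is.finite(r) && abs(r) > r_max) {
        offending <- list(kept = k, r = r)
        break
      }
    }
    if (is.null(offending)) {
      kept <- c(kept, nm)
    } else {
      dropped <- rbind(dropped,
                       data.frame(dropped = nm, kept = offending$kept,
                                  r = offending$r, stringsAsFactors = FALSE))
    }
  }
  structure(list(selected = kept, ranking = ranking,
                 removed_low_variance = attr(table, "removed_low_variance"),
                 removed_intercorrelated = dropped,
                 r_max = r_max),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", length(x$selected), " surviving descriptors\n",
      sep = "")
  sel <- x$ranking[x$ranking$descriptor %in% x$selected, ]
  print.data.frame(utils::head(sel, 10), row.names = FALSE)
  if (nrow(x$removed_intercorrelated)) {
    cat("pruned (|r| > ", x$r_max, "):\n", sep = "")
    print.data.frame(x$removed_intercorrelated, row.names = FALSE)
  }
  invisible(x)
}

#' Select the top-k surviving descriptors
#'
#' @param result A `selection_result`.
#' @param k Number of descriptors to return (default 3).
#' @return Character vector of the first `min(k, available)` surviving
#'   descriptor names, in ranking order.
#' @export
select_top_k <- function(result, k = 3) {
  stopifnot(inherits(result, "selection_result"))
  if (k < 1) stop("k must be >= 1")
  utils::head(result$selected, k)
}

#' Full filter-based selection pipeline
#'
#' Variance filter, correlation ranking, inter-correlation pruning and
#' top-k pick in one call.
#'
#' @inheritParams rank_by_target_correlation
#' @param var_threshold Variance threshold.
#' @param r_max Pairwise-correlation pruning ceiling.
#' @param k Number of descriptors selected.
#' @return A `selection_result` with an extra `top_k` element.
#' @export
select_descriptors <- function(table, y, var_threshold = 0.5, r_max = 0.9,
                               k = 3, mask = NULL) {
  filtered <- variance_filter(table, var_threshold)
  if (ncol(filtered) == 0L) stop("no descriptor passed the variance filter")
  ranking <- rank_by_target_correlation(filtered, y, mask = mask)
  result <- prune_intercorrelated(ranking, filtered, r_max)
  result$top_k <- select_top_k(result, k)
  result
}

#' Correlation-matched noisy descriptor
#'
#' Adds zero-mean Gaussian noise to a descriptor so that its correlation
#' with the target shrinks from `r_d = cor(d, y)` to `r_target`. The noise
#' standard deviation follows the attenuation identity
#' `cor(d + e, y) = r_d * sd(d) / sqrt(sd(d)^2 + s^2)`, giving
#' `s = sd(d) * sqrt((r_d / r_target)^2 - 1)`.
#'
#' @param d Numeric descriptor vector.
#' @param y Numeric target vector.
#' @param r_target Desired correlation; must share the sign of `cor(d, y)`
#'   and not exceed it in magnitude.
#' @param seed Integer seed for the noise draw.
#' @return `d` plus noise; exactly `d` when `r_target == cor(d, y)`.
#' @export
make_noisy_descriptor <- function(d, y, r_target, seed = 1L) {
  stopifnot(length(d) == length(y))
  r_d <- stats::cor(d, y)
  if (r_target == 0) stop("r_target must be non-zero")
  if (sign(r_target) != sign(r_d)) {
    stop("r_target must have the same sign as cor(d, y) = ", round(r_d, 4))
  }
  if (abs(r_target) > abs(r_d)) {
    stop("infeasible: |r_target| = ", abs(r_target),
         " exceeds |cor(d, y)| = ", round(abs(r_d), 4),
         "; noise can only reduce the correlation")
  }
  s <- stats::sd(d) * sqrt((r_d / r_target)^2 - 1)
  if (s == 0) return(d)
  with_seed(seed, d + stats::rnorm(length(d), 0, s))
}
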