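#' Pseudo-bulk aggregation of a cell-by-feature count matrix
#'
#' Sums counts over all cells sharing the same grouping key (by default
#' cell type, age and biological replicate), yielding bulk-like count
#' profiles. Sums are exact integer sums; the grand total is conserved.
#'
#' @param matrix count matrix, cells x features, cell ids as rownames.
#' @param cells per-cell metadata with `cell_id` and the `keys` columns.
#' @param keys grouping columns (default `c("cell_type", "age",
#'   "replicate")`).
#' @return A list of class `PseudobulkCounts`: `counts` (features x
#'   groups dense matrix) and `groups` (data frame, one row per column of
#'   `counts`, with the key columns).
#' @export
aggregate_pseudobulk <- function(matrix, cells,
                                 keys = c("cell_type", "age", "replicate")) {
  assert_columns(cells, c("cell_id", keys), "cells")
  if (is.null(rownames(matrix))) stop("matrix must carry cell ids as rownames")
  miss <- setdiff(rownames(matrix), cells$cell_id)
  if (length(miss)) {
    stop("cells missing metadata: ", paste(head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5) else "")
  }
  meta <- cells[match(rownames(matrix), cells$cell_id), , drop = FALSE]
  key <- interaction(meta[keys], drop = TRUE, sep = "\r")
  ind <- Matrix::fac2sparse(key)                    # groups x cells
  counts <- t(as.matrix(ind %*% matrix))            # features x groups
  lev <- as.data.frame(do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE)),
                       stringsAsFactors = FALSE)
  names(lev) <- keys
  colnames(counts) <- levels(key)
  rownames(counts) <- colnames(matrix)
  structure(list(counts = counts, groups = lev), class = "PseudobulkCounts")
}

#' Median-of-ratios size factors
#'
#' For each group (column), the size factor is the median over features of
#' the ratio of the group's count to the feature's geometric mean across
#' groups, taken over features whose count is positive in every group
#' (finite geometric mean). Size factors are defined only up to a common
#' scale; they are rescaled to median 1, so a group whose counts are a
#' doubled copy of the others gets factor 2 while the others keep 1.
#'
#' @param counts a `PseudobulkCounts` or a features-x-groups matrix.
#' @return Named numeric vector of positive size factors, one per group.
#' @export
size_factors_median_of_ratios <- function(counts) {
  m <- if (inherits(counts, "PseudobulkCounts")) counts$counts else as.matrix(counts)
  if (any(colSums(m) == 0)) stop("a group has all-zero counts")
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) stop("no feature has nonzero counts in every group")
  logm <- log(m[pos, , drop = FALSE])
  loggeo <- rowMeans(logm)
  sf <- apply(logm, 2, function(col) exp(median(col - loggeo)))
  if (any(sf <= 0)) stop("non-positive size factor")
  sf / median(sf)
}

## Statistic for the permutation test: log2 ratio of pseudocounted mean
## normalized counts, old over young.
te_lfc_stat <- function(norm, old_idx, young_idx, pseudocount = 0.5) {
  log2((rowMeans(norm[, old_idx, drop = FALSE]) + pseudocount) /
         (rowMeans(norm[, young_idx, drop = FALSE]) + pseudocount))
}

#' Permutation test for age-differential features in pseudo-bulk counts
#'
#' Counts are normalized by median-of-ratios size factors; the per-feature
#' statistic is `log2((mean_old + 0.5) / (mean_young + 0.5))` of normalized
#' means. Replicate age labels are permuted: exhaustively over all
#' distinct group assignments when their number does not exceed
#' `n_permutations`, otherwise by Monte-Carlo with the `+1` correction.
#'
#' Two null modes are available. `"per_feature"` compares each feature's
#' statistic to its own permutation distribution; its p-values are exact
#' but floored at 2 / (number of assignments) — with 4 vs 4 replicates
#' that floor is 2/70, too coarse for FDR control across many features.
#' `"pooled"` pools the permuted statistics of all features into one null
#' (standard practice at small replicate counts), giving p-value
#' resolution ~1/(features x permutations) at the cost of assuming
#' features share a null scale.
#'
#' @param counts a `PseudobulkCounts` restricted to one cell type, or a
#'   features-x-samples matrix.
#' @param ages vector giving each column's age.
#' @param young,old the two age labels to compare.
#' @param n_permutations Monte-Carlo budget (default 10000).
#' @param seed integer seed for Monte-Carlo permutations.
#' @param null `"per_feature"` or `"pooled"`.
#' @param pseudocount added to normalized means before the log (default
#'   0.5).
#' @return A data frame: `feature_id`, `log2_fold_change`, `p_value`,
#'   `adjusted_p` (BH across features); attribute `n_assignments` gives
#'   the size of the permutation group, `exhaustive` whether it was fully
#'   enumerated.
#' @export
test_te_differential <- function(counts, ages, young, old,
                                 n_permutations = 10000, seed = 1L,
                                 null = c("per_feature", "pooled"),
                                 pseudocount = 0.5) {
  null <- match.arg(null)
  m <- if (inherits(counts, "PseudobulkCounts")) counts$counts else as.matrix(counts)
  if (inherits(counts, "PseudobulkCounts") && missing(ages)) {
    ages <- counts$groups$age
  }
  ages <- as.character(ages)
  keep <- ages %in% as.character(c(young, old))
  m <- m[, keep, drop = FALSE]
  ages <- ages[keep]
  old_idx <- which(ages == as.character(old))
  young_idx <- which(ages == as.character(young))
  if (length(old_idx) < 2 || length(young_idx) < 2) {
    stop("need >= 2 replicates per age group")
  }
  sf <- size_factors_median_of_ratios(m)
  norm <- sweep(m, 2, sf, "/")
  n_s <- ncol(norm)
  obs <- te_lfc_stat(norm, old_idx, young_idx, pseudocount)
  assignments <- utils::combn(n_s, length(old_idx))
  n_assign <- ncol(assignments)
  exhaustive <- n_assign <= n_permutations
  perm_stats <- if (exhaustive) {
    vapply(seq_len(n_assign), function(j) {
      oi <- assignments[, j]
      te_lfc_stat(norm, oi, setdiff(seq_len(n_s), oi), pseudocount)
    }, numeric(nrow(norm)))
  } else {
    with_seed(seed, vapply(seq_len(n_permutations), function(j) {
      oi <- sample.int(n_s, length(old_idx))
      te_lfc_stat(norm, oi, setdiff(seq_len(n_s), oi), pseudocount)
    }, numeric(nrow(norm))))
  }
  if (is.null(dim(perm_stats))) perm_stats <- matrix(perm_stats, nrow = 1)
  abs_obs <- abs(obs)
  if (null == "per_feature") {
    if (exhaustive) {
      p <- rowMeans(abs(perm_stats) >= abs_obs - 1e-12)
    } else {
      p <- (1 + rowSums(abs(perm_stats) >= abs_obs - 1e-12)) /
        (n_permutations + 1)
    }
  } else {
    ## pool null statistics across features, excluding the observed
    ## assignment and its mirror (which reproduce +/- the observed value)
    if (exhaustive) {
      is_obs <- vapply(seq_len(n_assign), function(j) {
        setequal(assignments[, j], old_idx) ||
          setequal(assignments[, j], young_idx)
      }, logical(1))
      pool <- abs(perm_stats[, !is_obs, drop = FALSE])
    } else {
      pool <- abs(perm_stats)
    }
    pool <- as.vector(pool)
    ord <- sort(pool)
    exceed <- length(pool) - findInterval(abs_obs - 1e-12, ord)
    p <- (1 + exceed) / (1 + length(pool))
  }
  out <- data.frame(feature_id = rownames(norm) %||% seq_len(nrow(norm)),
                    log2_fold_change = obs, p_value = p,
                    adjusted_p = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_assignments") <- n_assign
  attr(out, "exhaustive") <- exhaustive
  out
}
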