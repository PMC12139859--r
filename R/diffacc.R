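#' Per-group accessible-cell fractions
#'
#' Collapses a binary cell-by-peak matrix to the fraction of cells in each
#' metadata group in which a peak is detected (has a nonzero entry) — the
#' pseudo-bulk representation on which the proportion-based differential
#' test operates. Groups with zero cells yield `NA` fractions flagged in
#' the `missing` column rather than zeros.
#'
#' @param matrix binary (or count) sparse matrix, cells x peaks, with cell
#'   ids as rownames.
#' @param cells data frame of per-cell metadata containing `cell_id` and
#'   every `group_by` column; each matrix row must appear in it.
#' @param group_by character vector of metadata column names to group by
#'   (e.g. `"age"`).
#' @return A `GroupFractionTable` data frame: `peak_id`, one column per
#'   grouping key, `n_cells`, `n_accessible`, `fraction`, `missing`.
#' @export
pseudobulk_fractions <- function(matrix, cells, group_by) {
  assert_columns(cells, c("cell_id", group_by), "cells")
  if (is.null(rownames(matrix))) stop("matrix must carry cell ids as rownames")
  miss <- setdiff(rownames(matrix), cells$cell_id)
  if (length(miss)) {
    stop("matrix rows absent from cell table: ",
         paste(head(miss, 5), collapse = ", "))
  }
  meta <- cells[match(rownames(matrix), cells$cell_id), , drop = FALSE]
  key <- interaction(meta[group_by], drop = FALSE, sep = "\r")
  bin <- (matrix > 0) * 1
  ind <- Matrix::fac2sparse(key)                 # levels x cells
  acc <- as.matrix(ind %*% bin)                  # levels x peaks
  n_cells <- as.vector(table(factor(key, levels = levels(key))))
  peak_ids <- colnames(matrix) %||% sprintf("peak_%06d", seq_len(ncol(matrix)))
  lev <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  lev <- as.data.frame(lev, stringsAsFactors = FALSE)
  names(lev) <- group_by
  out <- data.frame(
    peak_id = rep(peak_ids, each = length(levels(key))),
    lev[rep(seq_len(nrow(lev)), times = length(peak_ids)), , drop = FALSE],
    n_cells = rep(n_cells, times = length(peak_ids)),
    n_accessible = as.vector(acc),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$fraction <- ifelse(out$n_cells > 0, out$n_accessible / out$n_cells, NA_real_)
  out$missing <- out$n_cells == 0
  class(out) <- c("GroupFractionTable", "data.frame")
  out
}

## Two-sided two-proportion z-test with pooled variance; returns p = 1 when
## the pooled fraction is degenerate (0 or 1) or either group is empty.
two_proportion_z <- function(x1, n1, x2, n2) {
  phat <- (x1 + x2) / (n1 + n2)
  se <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (x2 / n2 - x1 / n1) / se, 0)
  2 * pnorm(-abs(z))
}

#' Proportion-based differential accessibility between two age groups
#'
#' For each peak, compares the fraction of accessible cells between a
#' young and an old group using a two-sided two-proportion z-test with
#' pooled variance. The effect size is
#' `log2((p_old + eps) / (p_young + eps))` with a small pseudocount `eps`
#' (default `1 / (n_young + n_old)`, scale-free shrinkage for empty
#' fractions). P-values are Benjamini-Hochberg adjusted within each
#' (`cell_type`, `region`, `sex`) family when those columns are present,
#' otherwise across all peaks. Peaks where either group has fewer than 2
#' cells are skipped with a warning. Direction is the sign of the fold
#' change; peaks with log2FC exactly 0 belong to neither direction (`NA`).
#'
#' @param fractions a [pseudobulk_fractions()] table whose grouping column
#'   `group_col` distinguishes the two ages.
#' @param young,old values of `group_col` identifying the two groups.
#' @param group_col name of the grouping column (default `"age"`).
#' @param pseudocount `eps`; `NULL` for the per-peak default.
#' @return A `DARTable` data frame: `peak_id`, any stratification columns,
#'   `n_young`, `n_old`, `frac_young`, `frac_old`, `log2_fold_change`,
#'   `p_value`, `adjusted_p`, `direction`.
#' @export
test_differential_accessibility <- function(fractions, young, old,
                                            group_col = "age",
                                            pseudocount = NULL) {
  assert_columns(fractions, c("peak_id", group_col, "n_cells",
                              "n_accessible"), "fractions")
  strata <- intersect(c("cell_type", "region", "sex"), names(fractions))
  strata <- setdiff(strata, group_col)
  g <- as.character(fractions[[group_col]])
  yg <- fractions[g == as.character(young), , drop = FALSE]
  og <- fractions[g == as.character(old), , drop = FALSE]
  if (nrow(yg) == 0 || nrow(og) == 0) {
    stop("groups ", young, " / ", old, " not found in column ", group_col)
  }
  key <- function(d) do.call(paste, c(d[c("peak_id", strata)], sep = "\r"))
  m <- match(key(yg), key(og))
  yg <- yg[!is.na(m), , drop = FALSE]
  og <- og[m[!is.na(m)], , drop = FALSE]
  small <- yg$n_cells < 2 | og$n_cells < 2
  if (any(small)) {
    warning(sum(small), " peak(s) skipped: a group has < 2 cells")
    yg <- yg[!small, , drop = FALSE]
    og <- og[!small, , drop = FALSE]
  }
  n1 <- yg$n_cells; n2 <- og$n_cells
  p1 <- yg$n_accessible / n1; p2 <- og$n_accessible / n2
  eps <- pseudocount %||% (1 / (n1 + n2))
  lfc <- log2((p2 + eps) / (p1 + eps))
  pv <- two_proportion_z(yg$n_accessible, n1, og$n_accessible, n2)
  out <- data.frame(peak_id = yg$peak_id,
                    yg[strata],
                    n_young = n1, n_old = n2,
                    frac_young = p1, frac_old = p2,
                    log2_fold_change = lfc, p_value = pv,
                    stringsAsFactors = FALSE, row.names = NULL)
  fam <- if (length(strata)) interaction(out[strata], drop = TRUE)
         else factor(rep(1L, nrow(out)))
  out$adjusted_p <- stats::ave(out$p_value, fam,
                               FUN = function(p) p.adjust(p, method = "BH"))
  out$direction <- ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", NA_character_))
  class(out) <- c("DARTable", "data.frame")
  out
}

#' Filter differential peaks by detection, effect size and FDR
#'
#' Keeps peaks detected in at least `min_detect` of cells in either age
#' group, with `|log2FC| >= min_abs_lfc` and adjusted p strictly below
#' `max_adj_p`. Both published effect-size thresholds are supported
#' through `min_abs_lfc` (0.25 for the primary screen, 0.5 for the
#' stricter reporting threshold); note the two conventions disagree, so
#' the choice is exposed rather than fixed.
#'
#' @param table a `DARTable` from [test_differential_accessibility()];
#'   the detection rule applies when the table carries `frac_young` /
#'   `frac_old` columns and is skipped otherwise (e.g. for externally
#'   supplied DAR tables without per-group fractions).
#' @param min_detect minimum detection fraction in either group
#'   (default 0.01).
#' @param min_abs_lfc minimum absolute log2 fold change (default 0.25).
#' @param max_adj_p adjusted-p cutoff, strict (default 0.01).
#' @return The filtered `DARTable`.
#' @export
filter_dars <- function(table, min_detect = 0.01, min_abs_lfc = 0.25,
                        max_adj_p = 0.01) {
  assert_columns(table, c("log2_fold_change", "adjusted_p"), "table")
  if (min_detect <= 0 || min_abs_lfc < 0 || max_adj_p <= 0) {
    stop("thresholds must be positive")
  }
  detect_ok <- if (all(c("frac_young", "frac_old") %in% names(table))) {
    pmax(table$frac_young, table$frac_old) >= min_detect
  } else TRUE
  keep <- detect_ok &
    abs(table$log2_fold_change) >= min_abs_lfc &
    table$adjusted_p < max_adj_p
  out <- table[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
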