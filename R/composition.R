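#' Per-sample cell-type proportions with sample weights
#'
#' A sample is one biological unit (by default the combination of region,
#' sex, replicate and age present in the metadata). Proportions are
#' cell-type counts over the sample total, so they sum to 1 within each
#' sample. Under the `"equal-sample"` scheme every sample at an age gets
#' weight `1 / (number of samples at that age)`, so large regions do not
#' dominate cross-sample averages; `"by-cells"` weights samples by their
#' cell counts instead.
#'
#' @param cells per-cell metadata with `cell_type`, `age` and the
#'   `sample_keys` columns.
#' @param weight_scheme `"equal-sample"` (default) or `"by-cells"`.
#' @param sample_keys columns (besides `age`) defining a sample; keys
#'   absent from `cells` are ignored.
#' @return A `ProportionTable` data frame: `sample`, `age`, `cell_type`,
#'   `n_cells`, `proportion`, `weight`.
#' @export
weighted_proportions <- function(cells,
                                 weight_scheme = c("equal-sample", "by-cells"),
                                 sample_keys = c("region", "sex", "replicate")) {
  weight_scheme <- match.arg(weight_scheme)
  assert_columns(cells, c("cell_type", "age"), "cells")
  sample_keys <- intersect(sample_keys, names(cells))
  sample <- interaction(cells[c(sample_keys, "age")], drop = TRUE, sep = "|")
  tab <- as.data.frame(table(sample = sample, cell_type = cells$cell_type),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n_cells"
  totals <- tapply(tab$n_cells, tab$sample, sum)
  empty <- names(totals)[totals == 0]
  if (length(empty)) {
    warning("dropping empty sample(s): ", paste(empty, collapse = ", "))
    tab <- tab[!(tab$sample %in% empty), , drop = FALSE]
    totals <- totals[setdiff(names(totals), empty)]
  }
  tab$proportion <- tab$n_cells / as.numeric(totals[tab$sample])
  age_of_sample <- tapply(as.character(cells$age), sample, function(a) a[1])
  tab$age <- as.character(age_of_sample[tab$sample])
  if (weight_scheme == "equal-sample") {
    n_at_age <- table(age_of_sample)
    tab$weight <- 1 / as.numeric(n_at_age[tab$age])
  } else {
    total_at_age <- tapply(as.numeric(totals), age_of_sample, sum)
    tab$weight <- as.numeric(totals[tab$sample]) /
      as.numeric(total_at_age[tab$age])
  }
  out <- tab[order(tab$age, tab$sample, tab$cell_type),
             c("sample", "age", "cell_type", "n_cells", "proportion", "weight")]
  rownames(out) <- NULL
  class(out) <- c("ProportionTable", "data.frame")
  out
}

#' Rank-sum test of age-associated change in cell-type proportions
#'
#' Two-sided Wilcoxon rank-sum test comparing per-sample proportions of a
#' cell type between two ages. The exact null distribution is used when
#' both groups have at most 12 samples and the data are tie-free
#' (full enumeration of rank assignments); otherwise the normal
#' approximation with tie correction is used. Direction is the sign of
#' the median difference (old minus young).
#'
#' @param props a [weighted_proportions()] table.
#' @param cell_types cell types to test (default all).
#' @param ages length-2 vector: (young, old) ages to compare
#'   (default `c(2, 18)`).
#' @return A data frame, one row per cell type: `cell_type`, `n_young`,
#'   `n_old`, `median_young`, `median_old`, `direction` (-1, 0 or +1),
#'   `p_value`, `exact` (logical).
#' @export
test_age_trend <- function(props, cell_types = NULL, ages = c(2, 18)) {
  assert_columns(props, c("cell_type", "age", "proportion"), "props")
  ages <- as.character(ages)
  cell_types <- cell_types %||% unique(props$cell_type)
  out <- do.call(rbind, lapply(cell_types, function(ct) {
    yi <- props$proportion[props$cell_type == ct & props$age == ages[1]]
    oi <- props$proportion[props$cell_type == ct & props$age == ages[2]]
    if (length(yi) < 2 || length(oi) < 2) {
      stop("cell type '", ct, "' has a group with fewer than 2 samples")
    }
    use_exact <- length(yi) <= 12 && length(oi) <= 12 &&
      !any(duplicated(c(yi, oi)))
    if (length(unique(c(yi, oi))) == 1L) {
      # all proportions identical: no evidence of any shift
      wt <- list(p.value = 1)
    } else {
      wt <- suppressWarnings(
        wilcox.test(oi, yi, alternative = "two.sided", exact = use_exact,
                    correct = !use_exact))
    }
    data.frame(cell_type = ct, n_young = length(yi), n_old = length(oi),
               median_young = median(yi), median_old = median(oi),
               direction = sign(median(oi) - median(yi)),
               p_value = wt$p.value, exact = use_exact,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
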