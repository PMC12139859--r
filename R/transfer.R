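#' Mean z-scored expression profile per cluster
#'
#' Z-scores each gene across *all* cells jointly ((x - mean) / sd), then
#' averages within cluster. Genes with zero standard deviation carry no
#' information for profile correlation and are excluded; their ids are
#' returned in the `excluded_genes` attribute.
#'
#' @param expr cell-by-gene expression matrix (rows = cells).
#' @param clusters vector of cluster ids, one per cell.
#' @return A `ClusterProfileSet` matrix, clusters x genes, with attribute
#'   `excluded_genes`.
#' @export
cluster_mean_zscore <- function(expr, clusters) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2) stop("need at least 2 cells")
  if (length(clusters) != nrow(expr)) {
    stop("clusters must have one entry per cell")
  }
  mu <- colMeans(expr)
  sdv <- apply(expr, 2, sd)
  keep <- is.finite(sdv) & sdv > 0
  excluded <- colnames(expr)[!keep] %||% which(!keep)
  z <- sweep(sweep(expr[, keep, drop = FALSE], 2, mu[keep], "-"),
             2, sdv[keep], "/")
  cl <- factor(clusters)
  prof <- rowsum(z, cl) / as.vector(table(cl))
  attr(prof, "excluded_genes") <- excluded
  class(prof) <- c("ClusterProfileSet", class(prof))
  prof
}

#' Assign reference labels to query clusters by profile correlation
#'
#' Computes the Pearson correlation between each query and reference
#' cluster profile over their shared genes (sorted intersection; at least
#' 2 required) and assigns each query cluster the label of its maximally
#' correlated reference cluster. Exact ties leave the cluster unassigned
#' (`NA`).
#'
#' @param query,reference profile matrices (clusters x genes) with gene
#'   names as colnames, e.g. from [cluster_mean_zscore()] or
#'   [simulate_label_profiles()].
#' @return A data frame: `query_cluster`, `label`, `correlation`.
#' @export
correlate_and_assign <- function(query, reference) {
  shared <- sort(intersect(colnames(query), colnames(reference)))
  if (length(shared) < 2) stop("fewer than 2 shared genes")
  q <- query[, shared, drop = FALSE]
  r <- reference[, shared, drop = FALSE]
  cc <- cor(t(q), t(r))   # query x reference
  best <- apply(cc, 1, function(row) {
    m <- max(row)
    hits <- which(row >= m - 0)
    if (length(hits) != 1L) NA_integer_ else hits
  })
  data.frame(
    query_cluster = rownames(q) %||% seq_len(nrow(q)),
    label = ifelse(is.na(best), NA_character_, rownames(r)[best]),
    correlation = ifelse(is.na(best), NA_real_,
                         cc[cbind(seq_len(nrow(cc)), best)]),
    stringsAsFactors = FALSE
  )
}

#' Confidence-gated majority-vote refinement of subcluster labels
#'
#' Within each subcluster, only cells with confidence strictly above
#' `score_min` vote. If the modal label's share of those high-confidence
#' voters exceeds `majority_min` (strict; default 0.5, i.e. a strict
#' majority — set `rule = "plurality"` to accept the modal label
#' regardless of share), every cell of the subcluster receives it;
#' otherwise the subcluster is ambiguous and removed. Subclusters with no
#' high-confidence cells are removed. Modal-label ties are removed.
#'
#' @param preds data frame: `cell_id`, `subcluster_id`, `predicted_label`,
#'   `score` in `[0, 1]`.
#' @param score_min confidence gate, strict `>` (default 0.85).
#' @param majority_min required modal share among voters, strict `>`
#'   (default 0.5); ignored under `rule = "plurality"`.
#' @param rule `"strict"` majority or `"plurality"`.
#' @return A list: `assignments` (data frame `cell_id`, `subcluster_id`,
#'   `label`) and `dropped` (data frame `subcluster_id`, `reason`).
#' @export
refine_subcluster_labels <- function(preds, score_min = 0.85,
                                     majority_min = 0.5,
                                     rule = c("strict", "plurality")) {
  rule <- match.arg(rule)
  assert_columns(preds, c("cell_id", "subcluster_id", "predicted_label",
                          "score"), "preds")
  if (any(preds$score < 0 | preds$score > 1)) stop("scores must lie in [0, 1]")
  assign <- list(); dropped <- list()
  for (sc in unique(preds$subcluster_id)) {
    p <- preds[preds$subcluster_id == sc, , drop = FALSE]
    hc <- p[p$score > score_min, , drop = FALSE]
    if (nrow(hc) == 0) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(subcluster_id = sc, reason = "no high-confidence cells")
      next
    }
    tab <- sort(table(hc$predicted_label), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(subcluster_id = sc, reason = "modal label tie")
      next
    }
    share <- tab[1] / nrow(hc)
    if (rule == "strict" && share <= majority_min) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(subcluster_id = sc, reason = "no strict majority")
      next
    }
    assign[[length(assign) + 1L]] <- data.frame(
      cell_id = p$cell_id, subcluster_id = sc,
      label = names(tab)[1], stringsAsFactors = FALSE)
  }
  list(
    assignments = if (length(assign)) do.call(rbind, assign)
                  else data.frame(cell_id = character(0),
                                  subcluster_id = character(0),
                                  label = character(0)),
    dropped = if (length(dropped)) do.call(rbind, dropped)
              else data.frame(subcluster_id = character(0),
                              reason = character(0))
  )
}

#' Consistency rule for subcluster label assignment
#'
#' A subcluster is assigned a label only when strictly more than
#' `consistency_min` of *all* its cells were mapped to that single
#' reference label; otherwise it is flagged for manual annotation.
#'
#' @param preds data frame: `cell_id`, `subcluster_id`, `predicted_label`.
#' @param consistency_min required share, strict `>` (default 0.80).
#' @return A data frame, one row per subcluster: `subcluster_id`,
#'   `label` (`NA` when unassigned), `top_share`, `n_cells`, `assigned`.
#' @export
consistency_assign <- function(preds, consistency_min = 0.80) {
  assert_columns(preds, c("cell_id", "subcluster_id", "predicted_label"),
                 "preds")
  out <- do.call(rbind, lapply(unique(preds$subcluster_id), function(sc) {
    p <- preds[preds$subcluster_id == sc, , drop = FALSE]
    tab <- sort(table(p$predicted_label), decreasing = TRUE)
    share <- tab[1] / nrow(p)
    ok <- share > consistency_min &&
      !(length(tab) > 1 && tab[1] == tab[2])
    data.frame(subcluster_id = sc,
               label = if (ok) names(tab)[1] else NA_character_,
               top_share = as.numeric(share), n_cells = nrow(p),
               assigned = ok, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
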