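#' Flag regions overlapping a domain set
#'
#' Half-open interval arithmetic: a region overlaps iff the intersection
#' is at least 1 bp, so `[100,200)` does not touch `[200,300)`.
#'
#' @param regions,domains `GRanges` on the same genome.
#' @return A data frame with one row per region: `overlaps` (logical) and
#'   `overlap_bp` (total intersected bp across all domains).
#' @export
overlap_flags <- function(regions, domains) {
  shared <- intersect(unique(as.character(GenomeInfoDb::seqnames(regions))),
                      unique(as.character(GenomeInfoDb::seqnames(domains))))
  if (length(regions) && length(domains) && length(shared) == 0) {
    stop("regions and domains share no chromosome names; ",
         "mismatched chromosome namespaces")
  }
  hits <- GenomicRanges::findOverlaps(regions, domains, minoverlap = 1L)
  bp <- rep(0, length(regions))
  if (length(hits)) {
    ov <- GenomicRanges::pintersect(
      regions[S4Vectors::queryHits(hits)],
      domains[S4Vectors::subjectHits(hits)])
    bp_hit <- as.numeric(GenomicRanges::width(ov))
    agg <- rowsum(bp_hit, S4Vectors::queryHits(hits))
    bp[as.integer(rownames(agg))] <- agg[, 1]
  }
  data.frame(overlaps = bp > 0, overlap_bp = bp)
}

## Fast in-domain test for half-open intervals [s, s+w) against sorted,
## reduced domains on one chromosome. Used inside the permutation loop
## where GRanges construction per permutation would dominate runtime.
interval_hits_sorted <- function(s, w, dom_start, dom_end) {
  if (length(dom_start) == 0) return(rep(FALSE, length(s)))
  i <- findInterval(s, dom_start)
  left <- i >= 1 & dom_end[pmax(i, 1)] > s
  right <- i < length(dom_start) & dom_start[pmin(i + 1, length(dom_start))] < s + w
  left | right
}

#' Enrichment of a region set in genomic domains
#'
#' Compares the fraction of regions overlapping domains (any-bp
#' intersection) with the fraction of the genome the domains cover. Two
#' null models are reported: an upper-tail binomial p-value
#' `P(X >= n_overlapping | n_total, coverage)`, and a permutation p-value
#' from uniformly re-placing each region on its own chromosome with its
#' length preserved (controls for chromosome-level region density), with
#' the standard `+1/(n+1)` correction.
#'
#' @param regions `GRanges` to test (e.g. DARs or hotspot calls).
#' @param domains `GRanges` of domains (e.g. H3K9me3 blocks).
#' @param layout a [genome_layout()].
#' @param n_permutations number of length-preserving permutations
#'   (default 1000); 0 skips the permutation null.
#' @param seed integer seed for the permutations.
#' @return A list of class `EnrichmentResult`: `n_total`, `n_overlapping`,
#'   `observed_fraction`, `genome_coverage_fraction`, `enrichment_ratio`,
#'   `binomial_p`, `permutation_p`, `n_permutations`, `undefined`.
#' @export
domain_enrichment <- function(regions, domains, layout,
                              n_permutations = 1000, seed = 1L) {
  if (length(regions) == 0) stop("region set is empty")
  check_chroms(GenomeInfoDb::seqnames(regions), layout, "regions")
  dom_red <- GenomicRanges::reduce(domains)
  coverage <- sum(as.numeric(GenomicRanges::width(dom_red))) / genome_length(layout)
  if (length(dom_red) == 0 || coverage == 0) {
    out <- list(n_total = length(regions), n_overlapping = NA_integer_,
                observed_fraction = NA_real_, genome_coverage_fraction = 0,
                enrichment_ratio = NA_real_, binomial_p = NA_real_,
                permutation_p = NA_real_, n_permutations = 0L,
                undefined = TRUE)
    class(out) <- "EnrichmentResult"
    return(out)
  }
  n <- length(regions)
  n_ov <- sum(overlap_flags(regions, dom_red)$overlaps)
  obs_frac <- n_ov / n
  binom_p <- pbinom(n_ov - 1, n, coverage, lower.tail = FALSE)
  perm_p <- NA_real_
  if (n_permutations > 0) {
    perm_counts <- permuted_overlap_counts(regions, dom_red, layout,
                                           n_permutations, seed)
    perm_p <- (1 + sum(perm_counts >= n_ov)) / (n_permutations + 1)
  }
  out <- list(n_total = n, n_overlapping = n_ov,
              observed_fraction = obs_frac,
              genome_coverage_fraction = coverage,
              enrichment_ratio = obs_frac / coverage,
              binomial_p = binom_p, permutation_p = perm_p,
              n_permutations = as.integer(n_permutations),
              undefined = FALSE)
  class(out) <- "EnrichmentResult"
  out
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("EnrichmentResult: undefined (empty domain set)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "EnrichmentResult: %d/%d regions in domains (%.1f%%) vs %.2f%% genome coverage\n",
    x$n_overlapping, x$n_total, 100 * x$observed_fraction,
    100 * x$genome_coverage_fraction))
  cat(sprintf("  enrichment ratio %.2f, binomial p %.3g, permutation p %s (n = %d)\n",
              x$enrichment_ratio, x$binomial_p,
              format(x$permutation_p, digits = 3), x$n_permutations))
  invisible(x)
}

## Vector of overlap counts across length-preserving uniform permutations.
permuted_overlap_counts <- function(regions, dom_red, layout, B, seed) {
  chrom <- as.character(GenomeInfoDb::seqnames(regions))
  w <- as.numeric(GenomicRanges::width(regions))
  with_seed(seed, {
    total <- numeric(B)
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      L <- layout$length[match(ch, layout$chrom)]
      dsel <- as.character(GenomeInfoDb::seqnames(dom_red)) == ch
      ds <- bed_start(dom_red[dsel]); de <- bed_end(dom_red[dsel])
      o <- order(ds); ds <- ds[o]; de <- de[o]
      wi <- w[sel]; m <- length(wi)
      s <- floor(runif(m * B, 0, rep(pmax(L - wi, 1), B)))
      hit <- interval_hits_sorted(s, rep(wi, B), ds, de)
      total <- total + rowsum(as.numeric(hit), rep(seq_len(B), each = m))[, 1]
    }
    total
  })
}

#' Two-sided 2x2 exact association test
#'
#' Exact conditional test of association in a 2x2 table by hypergeometric
#' enumeration: the two-sided p-value sums the probabilities of all
#' tables (with the observed margins) no more likely than the observed
#' one.
#'
#' @param a,b,c,d cell counts of the table `rbind(c(a, b), c(c, d))`.
#' @return The two-sided exact p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  K <- a + b          # row 1 total
  n <- a + b + c + d
  k <- a + c          # column 1 total
  x <- max(0, k - (n - K)):min(k, K)
  probs <- dhyper(x, K, n - K, k)
  p_obs <- dhyper(a, K, n - K, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Direction split of DARs inside vs outside domains
#'
#' Partitions filtered DARs by direction (up/down) and domain membership
#' (any-bp overlap), per cell type, reporting the up-fraction in each
#' stratum and a two-sided exact 2x2 association p-value. Inside
#' heterochromatin, aging peaks are expected to skew up; outside, the
#' split should be roughly balanced.
#'
#' @param dars `DARTable` with `chrom`, `start`, `end`, `direction` and
#'   optionally `cell_type`.
#' @param domains `GRanges` of domains.
#' @return A `DirectionSplit` data frame, one row per cell type:
#'   `up_in`, `down_in`, `up_out`, `down_out`, `up_fraction_in`,
#'   `up_fraction_out`, `fisher_p`.
#' @export
direction_split <- function(dars, domains) {
  assert_columns(dars, c("chrom", "start", "end", "direction"), "dars")
  ct <- dars$cell_type %||% rep("all", nrow(dars))
  gr <- region_set(dars$chrom, dars$start, dars$end)
  inside <- if (length(domains)) overlap_flags(gr, domains)$overlaps
            else rep(FALSE, nrow(dars))
  up <- dars$direction == "up"
  out <- do.call(rbind, lapply(unique(ct), function(cc) {
    s <- ct == cc
    a <- sum(s & up & inside); b <- sum(s & !up & inside)
    cN <- sum(s & up & !inside); d <- sum(s & !up & !inside)
    data.frame(cell_type = cc, up_in = a, down_in = b, up_out = cN,
               down_out = d,
               up_fraction_in = if (a + b > 0) a / (a + b) else NA_real_,
               up_fraction_out = if (cN + d > 0) cN / (cN + d) else NA_real_,
               fisher_p = fisher_exact_2x2(a, b, cN, d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("DirectionSplit", "data.frame")
  out
}

#' Biotype composition of top-ranked differential genes
#'
#' For each direction, takes the `top_n` most significant genes (ranked by
#' ascending adjusted p, ties broken by descending `|log2FC|`, then gene
#' id; or taken as-given with `ranked = TRUE`) and reports the fraction
#' whose biotype is `lncRNA` or `pseudogene`, plus the full per-biotype
#' breakdown. Genes missing from the biotype map count as `"unknown"`.
#'
#' @param ranked_genes data frame with `gene_id`, `direction` and (unless
#'   `ranked = TRUE`) `adjusted_p` and `log2_fold_change`.
#' @param biotypes data frame `gene_id`, `biotype`.
#' @param top_n number of genes per direction (default 100).
#' @param ranked if `TRUE`, `ranked_genes` is already in rank order within
#'   each direction.
#' @param repressed_biotypes biotypes counted in the headline fraction
#'   (default `c("lncRNA", "pseudogene")`).
#' @return A list with `summary` (per direction: `n`,
#'   `repressed_fraction`) and `breakdown` (direction x biotype counts and
#'   fractions).
#' @export
biotype_top_composition <- function(ranked_genes, biotypes, top_n = 100,
                                    ranked = FALSE,
                                    repressed_biotypes = c("lncRNA", "pseudogene")) {
  assert_columns(ranked_genes, c("gene_id", "direction"), "ranked_genes")
  assert_columns(biotypes, c("gene_id", "biotype"), "biotypes")
  res_sum <- list(); res_brk <- list()
  for (dir in unique(ranked_genes$direction)) {
    g <- ranked_genes[ranked_genes$direction == dir, , drop = FALSE]
    if (top_n > nrow(g)) {
      stop("top_n = ", top_n, " exceeds the ", nrow(g),
           " genes available for direction '", dir, "'")
    }
    if (!ranked) {
      assert_columns(g, c("adjusted_p", "log2_fold_change"), "ranked_genes")
      g <- g[order(g$adjusted_p, -abs(g$log2_fold_change), g$gene_id), ,
             drop = FALSE]
    }
    top <- g$gene_id[seq_len(top_n)]
    bt <- biotypes$biotype[match(top, biotypes$gene_id)]
    bt[is.na(bt)] <- "unknown"
    tab <- table(bt)
    res_sum[[dir]] <- data.frame(
      direction = dir, n = top_n,
      repressed_fraction = sum(bt %in% repressed_biotypes) / top_n,
      stringsAsFactors = FALSE)
    res_brk[[dir]] <- data.frame(
      direction = dir, biotype = names(tab),
      count = as.integer(tab), fraction = as.integer(tab) / top_n,
      stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(res_sum, list(make.row.names = FALSE))),
       breakdown = do.call(rbind, c(res_brk, list(make.row.names = FALSE))))
}
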