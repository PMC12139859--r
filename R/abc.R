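#' Candidate elements per gene by TSS distance
#'
#' A peak is a candidate regulatory element for a gene when its midpoint
#' lies strictly within `window_bp` of the gene's transcription start
#' site on the same chromosome. The TSS is the annotated gene start on
#' the annotated strand (the `end` coordinate for minus-strand genes).
#'
#' @param peaks `GRanges` of elements with a `name` metadata column
#'   (element ids), or a data frame with `element_id`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param genes data frame: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param window_bp candidate window around the TSS, strict `<`
#'   (default 5 Mb).
#' @return A named list mapping `gene_id` to a character vector of
#'   candidate element ids (genes with no candidates map to
#'   `character(0)`).
#' @export
candidate_elements <- function(peaks, genes, window_bp = 5e6) {
  if (is.data.frame(peaks)) {
    assert_columns(peaks, c("element_id", "chrom", "start", "end"), "peaks")
    pk <- peaks
  } else {
    pk <- data.frame(element_id = peaks$name,
                     chrom = as.character(GenomeInfoDb::seqnames(peaks)),
                     start = bed_start(peaks), end = bed_end(peaks),
                     stringsAsFactors = FALSE)
  }
  assert_columns(genes, c("gene_id", "chrom", "start", "end", "strand"),
                 "genes")
  mid <- floor((pk$start + pk$end) / 2)
  tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  ## window query via IRanges overlap on midpoints
  qry <- GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(mid + 1, mid + 1))
  win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(tss - window_bp + 1, 0) + 1, tss + window_bp))
  hits <- GenomicRanges::findOverlaps(qry, win)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ## enforce the strict-< rule exactly (overlap query is inclusive)
  keep <- abs(mid[qh] - tss[sh]) < window_bp
  qh <- qh[keep]; sh <- sh[keep]
  out <- setNames(vector("list", nrow(genes)), genes$gene_id)
  out[] <- list(character(0))
  if (length(qh)) {
    sp <- split(pk$element_id[qh], genes$gene_id[sh])
    out[names(sp)] <- lapply(sp, unique)
  }
  out
}

#' Activity-By-Contact scores linking elements to genes
#'
#' For each gene `g` with candidate element set `E(g)`, the ABC score of
#' element `e` is
#' `A_e * C_{e,g} / sum over e' in E(g) of A_e' * C_{e',g}`,
#' where `A` is the element's activity (accessibility signal) and `C` the
#' normalized element-gene contact frequency. Scores over a gene's
#' candidates sum to 1 whenever any candidate has `A * C > 0`; genes with
#' an all-zero denominator yield no links. Candidate elements missing
#' from the contact table take `C = 0`.
#'
#' @param activities named numeric vector, activity per element id
#'   (>= 0).
#' @param contacts data frame: `element_id`, `gene_id`, `contact` (>= 0).
#' @param candidates named list gene_id -> element ids, e.g. from
#'   [candidate_elements()].
#' @param threshold optional minimum ABC score; links below it are
#'   dropped after normalization.
#' @return An `ABCLink` data frame sorted by gene then descending score:
#'   `gene_id`, `element_id`, `activity`, `contact`, `abc_score`.
#' @export
abc_scores <- function(activities, contacts, candidates, threshold = NULL) {
  assert_columns(contacts, c("element_id", "gene_id", "contact"), "contacts")
  if (any(activities < 0)) stop("negative activity")
  if (any(contacts$contact < 0)) stop("negative contact")
  if (any(lengths(candidates) == 0)) {
    candidates <- candidates[lengths(candidates) > 0]
  }
  ckey <- paste(contacts$element_id, contacts$gene_id, sep = "\r")
  out <- lapply(names(candidates), function(g) {
    els <- candidates[[g]]
    A <- activities[els]
    A[is.na(A)] <- 0
    C <- contacts$contact[match(paste(els, g, sep = "\r"), ckey)]
    C[is.na(C)] <- 0
    prod <- A * C
    denom <- sum(prod)
    if (denom == 0) return(NULL)
    data.frame(gene_id = g, element_id = els, activity = as.numeric(A),
               contact = C, abc_score = prod / denom,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), element_id = character(0),
                      activity = numeric(0), contact = numeric(0),
                      abc_score = numeric(0))
  }
  if (!is.null(threshold)) {
    out <- out[out$abc_score >= threshold, , drop = FALSE]
  }
  out <- out[order(out$gene_id, -out$abc_score), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ABCLink", "data.frame")
  out
}
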