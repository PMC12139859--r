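#' Genome layout: chromosome names and lengths
#'
#' The coordinate frame for all interval work in the package. A
#' `GenomeLayout` is a plain data frame with columns `chrom` and `length`
#' (base pairs), the in-memory equivalent of a `chrom.sizes` file. All
#' coordinates in the package are 0-based half-open (BED convention).
#'
#' @param chrom_names character vector of unique chromosome identifiers.
#' @param chrom_lengths positive integer vector of chromosome lengths (bp),
#'   one per chromosome.
#' @return A data frame of class `GenomeLayout` with columns `chrom`
#'   and `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths)) {
    stop("chrom_names and chrom_lengths must have equal length")
  }
  if (anyDuplicated(chrom_names)) stop("chromosome names must be unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop("chromosome lengths must be positive")
  }
  structure(
    data.frame(chrom = chrom_names, length = chrom_lengths,
               stringsAsFactors = FALSE),
    class = c("GenomeLayout", "data.frame")
  )
}

#' Total genome length of a layout
#' @param layout a [genome_layout()].
#' @return Numeric scalar, sum of chromosome lengths in bp.
#' @export
genome_length <- function(layout) sum(layout$length)

#' Convert a layout to a Seqinfo object
#' @param layout a [genome_layout()].
#' @return A [GenomeInfoDb::Seqinfo] with the layout's chromosomes.
#' @export
layout_seqinfo <- function(layout) {
  GenomeInfoDb::Seqinfo(seqnames = layout$chrom,
                        seqlengths = as.integer(layout$length))
}

## Check that a GRanges (or chrom vector) only uses chromosomes the layout
## knows about; used by operations that index bins by chromosome.
check_chroms <- function(chrom, layout, what = "regions") {
  bad <- setdiff(unique(as.character(chrom)), layout$chrom)
  if (length(bad)) {
    stop(what, " use chromosome(s) absent from the genome layout: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Build a GRanges region set on a layout
#'
#' Thin constructor turning 0-based half-open intervals into the 1-based
#' closed [GenomicRanges::GRanges] representation used internally. Extra
#' per-interval attributes are carried as metadata columns.
#'
#' @param chrom,start,end interval coordinates, 0-based half-open.
#' @param layout optional [genome_layout()]; when given, chromosome names
#'   are validated and seqlengths attached.
#' @param ... further equal-length vectors stored as metadata columns.
#' @return A `GRanges` object.
#' @export
region_set <- function(chrom, start, end, layout = NULL, ...) {
  if (any(end <= start)) stop("intervals must satisfy end > start")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.numeric(start) + 1,
                              end = as.numeric(end)),
    ...
  )
  if (!is.null(layout)) {
    check_chroms(GenomeInfoDb::seqnames(gr), layout)
    GenomeInfoDb::seqlevels(gr) <- layout$chrom
    GenomeInfoDb::seqlengths(gr) <- as.integer(layout$length)
  }
  gr
}

## 0-based starts / half-open ends of a GRanges, back in BED convention.
bed_start <- function(gr) GenomicRanges::start(gr) - 1
bed_end <- function(gr) GenomicRanges::end(gr)
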